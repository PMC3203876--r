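test_that("feature scaling is min-max on background with quadratic squares", {
  m <- matrix(seq(10, 30, length.out = 16), 4, 4)
  m[2, 2] <- 20   # an exact mid-range value to probe the scaling
  env <- env_stack(list(temp = m), 1)
  fs <- build_features(env)
  # value 20 in range [10, 30] scales to 0.5; its quadratic is 0.25
  cell <- which.min(abs(m - 20))
  expect_equal(unname(fs$F[cell, "temp.linear"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(fs$F[cell, "temp.quadratic"]), 0.25, tolerance = 1e-9)
  expect_true(all(fs$F[fs$background, ] >= 0 & fs$F[fs$background, ] <= 1))

  # constant layers are dropped with a warning
  env2 <- env_stack(list(a = m, k = matrix(3, 4, 4)), 1)
  expect_warning(fs2 <- build_features(env2), "constant")
  expect_setequal(unique(fs2$defs$layer), "a")
})

test_that("maximum-entropy fits match a generic convex-optimizer oracle", {
  for (seed in c(3, 17, 51)) {
    env <- tiny_env(2, c(18, 18), seed = seed)          # 324 cells
    occ <- simulate_species(env, true_niche(c(0.8, -0.5), 0.9), 30,
                            seed = seed + 1)
    fs <- build_features(env, kinds = "linear")          # <= 4 features
    fit <- fit_maxent(fs, occ, max_iter = 1000, tol = 1e-8)
    pres <- nichephylo:::presence_cells(fs, occ)
    Fsup <- fs$F[fs$support, , drop = FALSE]
    fbar <- colMeans(fs$F[pres, , drop = FALSE])
    sj <- apply(fs$F[fs$background, , drop = FALSE], 2, sd)
    beta <- sj / sqrt(length(pres))
    obj <- function(l) -sum(fbar * l) + log(sum(exp(Fsup %*% l))) +
      sum(beta * abs(l))
    op <- stats::optim(rep(0, ncol(Fsup)), obj, method = "BFGS",
                       control = list(maxit = 3000, reltol = 1e-14))
    expect_lt(abs(fit$objective - op$value), 1e-4)
    expect_lte(fit$objective, op$value + 1e-6)   # never worse than oracle
  }
})

test_that("degenerate fits behave as the theory demands", {
  env <- tiny_env(2, c(12, 12), seed = 9)
  occ <- simulate_species(env, true_niche(c(0.5, 0), 1), 20, seed = 2)
  fs <- build_features(env)

  # constant layers: uniform surface, zero gain
  envc <- env_stack(lapply(env$layers, function(m) m * 0 + 4),
                    env$cell_size_km)
  fsc <- suppressWarnings(build_features(envc))
  pres <- nichephylo:::presence_cells(fs, occ)
  mc <- fit_maxent(fsc, pres)
  expect_equal(mc$training_gain, 0)
  expect_true(all(abs(mc$raw[fsc$support] - 1 / length(fsc$support)) <
                    1e-12))

  # crushing regularization drives all weights to zero
  mb <- fit_maxent(fs, occ, reg_multiplier = 1e7)
  expect_equal(max(abs(mb$lambda)), 0)
  expect_equal(mb$training_gain, 0, tolerance = 1e-9)

  # normalization and objective monotonicity
  m <- fit_maxent(fs, occ, trace = TRUE)
  expect_equal(sum(m$raw), 1, tolerance = 1e-9)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
  expect_error(fit_maxent(fs, pres[1]), "fallback")
})

test_that("fitted weights recover the direction of a log-linear generating gradient", {
  # occurrences drawn from exp(b * feature): lambda on that feature should
  # recover the sign of b in nearly every seeded run
  env <- tiny_env(1, c(15, 15), seed = 13, corr_length_km = 3)
  fs <- build_features(env, kinds = "linear")
  f <- fs$F[, 1]
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    cells <- sample.int(225, 40, TRUE, prob = exp(3 * f) / sum(exp(3 * f)))
    fit <- fit_maxent(fs, cells, max_iter = 300)
    hits <- hits + (fit$lambda[1] > 0)
  }
  expect_gte(hits, 95L)
})

test_that("AUC is the tie-aware rank probability", {
  expect_equal(auc_scores(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_scores(c(3, 3), c(3, 3)), 0.5)
  expect_equal(auc_scores(c(0.9, 0.7), c(0.8, 0.1)), 0.75)
  expect_equal(auc_scores(c(0.9, 0.8), c(0.8, 0.1)), 0.875)
})

test_that("replicated models honour the averaging and SD contracts", {
  env <- tiny_env(2, c(12, 12), seed = 21)
  fs <- build_features(env)
  occ <- simulate_species(env, true_niche(c(0.4, 0.1), 0.9), 25, seed = 3)

  rep1 <- replicate_models(fs, occ, n_reps = 5, seed = 7)
  expect_equal(sum(rep1$model$raw), 1, tolerance = 1e-9)
  expect_false(is.null(rep1$model$replicate_sd))   # >= 8 presences
  expect_true(rep1$eval$auc >= 0 && rep1$eval$auc <= 1)

  # below 8 presences the replicate SD surface is not produced
  few <- nichephylo:::presence_cells(fs, occ)[1:5]
  repf <- replicate_models(fs, few, n_reps = 4, seed = 8)
  expect_null(repf$model$replicate_sd)

  expect_error(replicate_models(fs, few[1], n_reps = 2), "fallback")
})

test_that("jackknife contribution identifies informative and redundant layers", {
  set.seed(31)
  base <- tiny_env(1, c(15, 15), seed = 31, corr_length_km = 3)
  info <- base$layers[[1]]
  env <- env_stack(list(sig = info, dup = info,
                        noise = matrix(rnorm(225), 15, 15)), 1)
  fs <- build_features(env)
  f <- fs$F[, "sig.linear"]
  set.seed(5)
  cells <- sample.int(225, 40, TRUE, prob = exp(4 * f) / sum(exp(4 * f)))
  jk <- jackknife_contribution(fs, cells, max_iter = 300)
  expect_true(attr(jk, "top_layer") %in% c("sig", "dup"))
  # dropping one copy of a duplicated informative layer changes nothing
  full <- fit_maxent(fs, cells, max_iter = 300)$training_gain
  expect_lt(abs(jk$gain_without[jk$layer == "dup"] - full), 1e-3)
  expect_gt(jk$gain_alone[jk$layer == "sig"],
            jk$gain_alone[jk$layer == "noise"])
})

test_that("the range fallback surface is uniform inside the range", {
  env <- env_stack(list(a = matrix(rnorm(400), 20, 20)), 1)
  rng <- buffer_range(occurrence_set("s", cbind(10, 10)), 3)
  fb <- range_fallback_surface(rng, env)
  inside <- fb$raw[fb$raw > 0]
  expect_equal(sum(fb$raw), 1, tolerance = 1e-12)
  expect_true(all(abs(inside - inside[1]) < 1e-15))

  # a range covering the whole grid gives the uniform surface
  rngall <- buffer_range(occurrence_set("s", cbind(10, 10)), 100)
  fball <- range_fallback_surface(rngall, env)
  expect_equal(unique(round(fball$raw, 15)), 1 / 400)

  far <- buffer_range(occurrence_set("s", cbind(500, 500)), 2)
  expect_error(range_fallback_surface(far, env), "inside")
})
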