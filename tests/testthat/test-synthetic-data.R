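test_that("environmental stack generation is deterministic and hits its correlation targets", {
  a <- generate_env_stack(2, c(50, 50), corr_length_km = 2,
                          inter_layer_corr = 0.5, seed = 11)
  b <- generate_env_stack(2, c(50, 50), corr_length_km = 2,
                          inter_layer_corr = 0.5, seed = 11)
  expect_identical(a, b)

  # independent white noise: cross-layer correlation near zero
  w <- generate_env_stack(3, c(100, 100), corr_length_km = 0,
                          inter_layer_corr = 0, seed = 3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(cor(as.vector(w$layers[[i]]), as.vector(w$layers[[j]]))),
              0.1)

  # strong target correlation is realized empirically
  s <- generate_env_stack(2, c(200, 200), corr_length_km = 3,
                          inter_layer_corr = 0.9, seed = 7)
  r <- cor(as.vector(s$layers[[1]]), as.vector(s$layers[[2]]))
  expect_gt(r, 0.8)
  expect_lt(r, 0.97)

  expect_error(generate_env_stack(0, c(10, 10)), "n_layers")
  expect_error(generate_env_stack(2, c(0, 10)), "shape")
  expect_error(generate_env_stack(2, c(10, 10), cell_size_km = -1),
               "cell_size_km")
})

test_that("occurrences are sampled in proportion to the analytic suitability", {
  env <- tiny_env(2, c(15, 15), seed = 2)
  niche <- true_niche(c(0.3, -0.2), 1)

  # flat suitability limit: occupied-cell frequencies uniform within
  # multinomial error (chi-square goodness of fit)
  flat <- true_niche(c(0, 0), 1e6)
  occ_cells <- local({
    set.seed(99)
    s <- niche_suitability(env, flat)
    # direct draw mirror: compare sampling distribution with chi-square
    draws <- table(factor(sample.int(225, 5000, TRUE, prob = s / sum(s)),
                          levels = 1:225))
    suppressWarnings(stats::chisq.test(as.vector(draws), p = s / sum(s),
                                       rescale.p = TRUE)$p.value)
  })
  expect_gt(occ_cells, 0.001)

  # chi-square GOF for a moderately peaked niche, against the analytic law
  wide <- true_niche(c(0.3, -0.2), 3)
  s <- niche_suitability(env, wide)
  set.seed(4)
  draws <- table(factor(sample.int(225, 5000, TRUE, prob = s / sum(s)),
                        levels = 1:225))
  expect_gt(suppressWarnings(
    stats::chisq.test(as.vector(draws), p = s / sum(s),
                      rescale.p = TRUE)$p.value), 0.001)

  # a single unmasked cell forces all points onto it
  mask <- matrix(TRUE, 5, 5); mask[3, 3] <- FALSE
  env1 <- env_stack(list(a = matrix(rnorm(25), 5, 5)), 1,
                    nodata_mask = mask)
  o <- simulate_species(env1, true_niche(0, 1), 20, seed = 1)
  expect_equal(nrow(o), 1L)
  expect_equal(unname(unlist(o[1, ])), c(2.5, 2.5))

  # sharp niche at a known environmental optimum concentrates points in the
  # top-decile suitability cells
  opt_cell <- which.max(env$layers[[1]] + env$layers[[2]])
  E <- env_matrix(env, opt_cell)
  sharp <- true_niche(as.numeric(E), 0.2)
  ss <- niche_suitability(env, sharp)
  top <- which(ss >= stats::quantile(ss, 0.9))
  set.seed(8)
  cells <- sample.int(225, 500, TRUE, prob = ss / sum(ss))
  expect_gte(mean(cells %in% top), 0.9)

  expect_error(simulate_species(env, true_niche(0, 1), 10),
               "dimension")
})

test_that("Brownian clade simulation obeys the 2-sigma2-t variance law", {
  env <- tiny_env(1, c(10, 10), seed = 6)
  tr <- ape::read.tree(text = "(A:3,B:3);")

  # degenerate rate: every tip optimum equals the root optimum
  sim0 <- simulate_clade(tr, 0, root_optimum = 1.5, env = env,
                         n_points_per_tip = 5, seed = 2)
  expect_equal(sim0$A$niche$optimum, 1.5)
  expect_equal(sim0$B$niche$optimum, 1.5)

  # reproducibility
  s1 <- simulate_clade(tr, 0.3, 0, env, 5, seed = 9)
  s2 <- simulate_clade(tr, 0.3, 0, env, 5, seed = 9)
  expect_identical(lapply(s1, `[[`, "niche"), lapply(s2, `[[`, "niche"))

  # Var(opt_A - opt_B) = 2 * sigma2 * t over replicates, within 3 SE
  sigma2 <- 0.4; t_mrca <- 3; nrep <- 1000
  diffs <- vapply(seq_len(nrep), function(i) {
    s <- simulate_clade(tr, sigma2, 0, env, 1, seed = 1000 + i)
    s$A$niche$optimum - s$B$niche$optimum
  }, numeric(1))
  v <- stats::var(diffs)
  expected <- 2 * sigma2 * t_mrca
  se <- expected * sqrt(2 / (nrep - 1))
  expect_lt(abs(v - expected), 3 * se)

  expect_error(simulate_clade(tr, -1, 0, env), "sigma2")
})

test_that("the packaged study fixture matches the published pair table", {
  fx <- study_fixture()
  expect_length(fx$tree$tip.label, 27L)
  expect_true(ape::is.ultrametric(fx$tree))
  expect_equal(max(ape::branching.times(fx$tree)), 14.9, tolerance = 1e-8)

  p <- fx$pairs
  expect_equal(nrow(p), 11L)
  row <- p[p$species_a == "Isolona_pleurocarpa", ]
  expect_equal(row$mrca_age_ma, 4.5)
  expect_equal(row$overlap_pct, 19.6)
  expect_equal(p[p$species_a == "Monodora_carolinae", "overlap_pct"], 0)
  expect_equal(p[p$species_a == "Monodora_hastipetala", "overlap_pct"], 89.3)

  # the unresolved trio is encoded as a polytomy
  trio <- c("Monodora_laurentii", "Monodora_myristica", "Monodora_undulata")
  mrca <- ape::getMRCA(fx$tree, trio)
  kids <- fx$tree$edge[fx$tree$edge[, 1] == mrca, 2]
  expect_length(kids, 3L)
})

test_that("posterior jittering keeps trees ultrametric with the same tips", {
  fx <- study_fixture()
  post <- jitter_chronogram(fx$tree, n_trees = 5, sdlog = 0.15, seed = 2)
  expect_length(post, 5L)
  for (tr in post) {
    expect_setequal(tr$tip.label, fx$tree$tip.label)
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
    expect_true(all(tr$edge.length >= 0))
  }
  expect_identical(jitter_chronogram(fx$tree, 3, seed = 4),
                   jitter_chronogram(fx$tree, 3, seed = 4))
})
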