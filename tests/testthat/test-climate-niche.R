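test_that("environmental values are read at the correct cells and nodata rows drop", {
  # checkerboard layer: value = row + 100*col, lookup oracle by index math
  m <- outer(1:6, 1:5, function(r, c) r + 100 * c)
  env <- env_stack(list(chk = m), cell_size_km = 2)
  pts <- rbind(c(1, 1), c(3, 5), c(9.9, 11.9))   # cells (1,1), (3,2), (6,5)
  occ <- occurrence_set("s", pts)
  tt <- extract_values(env, occ)
  expect_equal(tt$chk, c(1 + 100, 3 + 200, 6 + 500))
  expect_equal(attr(tt, "n_dropped"), 0L)

  # constant layer reads constantly
  envc <- env_stack(list(k = matrix(7, 4, 4)), 1)
  ttc <- extract_values(envc, occurrence_set("s", rbind(c(0.5, 0.5),
                                                        c(3.5, 3.5))))
  expect_equal(ttc$k, c(7, 7))

  # a point on a masked cell is dropped and counted
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE
  envm <- env_stack(list(k = matrix(1, 4, 4)), 1, nodata_mask = mask)
  ttm <- extract_values(envm, occurrence_set("s", rbind(c(0.5, 0.5),
                                                        c(2.5, 2.5))))
  expect_equal(nrow(ttm), 1L)
  expect_equal(attr(ttm, "n_dropped"), 1L)
  expect_error(extract_values(envm, occurrence_set("s", cbind(0.5, 0.5))),
               "nodata")
})

test_that("species summaries apply the requested statistic", {
  tt <- structure(data.frame(a = c(1, 2, 3, 1, 2, 100),
                             species = rep(c("x", "y"), each = 3)),
                  class = c("trait_table", "data.frame"))
  expect_equal(species_summary(tt, "mean")["x", "a"], 2)
  expect_equal(species_summary(tt, "median")["y", "a"], 2)
  expect_equal(unname(species_summary(tt, "mean")["y", "a"]),
               mean(c(1, 2, 100)))
})

test_that("pair PCA reproduces the covariance eigenstructure", {
  # rank-1 data: two perfectly correlated layers -> PC1 explains 100%
  base <- rnorm(10)
  tt_a <- data.frame(l1 = base[1:5], l2 = 2 * base[1:5], species = "a")
  tt_b <- data.frame(l1 = base[6:10], l2 = 2 * base[6:10], species = "b")
  r <- pair_pca(tt_a, tt_b)
  expect_equal(r$pct_variance[1], 100, tolerance = 1e-8)

  # hand oracle: loadings match eigenvectors of the correlation matrix
  set.seed(42)
  A <- data.frame(l1 = rnorm(6), l2 = rnorm(6), l3 = rnorm(6),
                  species = "a")
  B <- data.frame(l1 = rnorm(6, 1), l2 = rnorm(6), l3 = rnorm(6, -1),
                  species = "b")
  r2 <- pair_pca(A, B)
  X <- scale(rbind(as.matrix(A[, 1:3]), as.matrix(B[, 1:3])))
  ev <- eigen(stats::cor(X))
  for (j in 1:3)   # eigenvectors defined up to sign
    expect_equal(abs(unname(r2$loadings[, j])), abs(ev$vectors[, j]),
                 tolerance = 1e-8)
  expect_equal(sort(r2$pct_variance, decreasing = TRUE), r2$pct_variance)

  # full reconstruction of the standardized data from all components
  recon <- r2$scores %*% t(r2$loadings)
  expect_equal(unname(recon), unname(X[, , drop = TRUE]), tolerance = 1e-8,
               ignore_attr = TRUE)

  # zero-variance layer dropped with warning
  Az <- cbind(A, lz = 1); Bz <- cbind(B, lz = 1)
  expect_warning(pair_pca(Az, Bz), "zero-variance")

  # near-isotropic cloud spreads variance roughly evenly
  set.seed(7)
  Ai <- data.frame(l1 = rnorm(300), l2 = rnorm(300), species = "a")
  Bi <- data.frame(l1 = rnorm(300), l2 = rnorm(300), species = "b")
  ri <- pair_pca(Ai, Bi)
  expect_true(all(abs(ri$pct_variance - 50) < 10))
})

test_that("Mann-Whitney test matches exact enumeration and the normal limit", {
  # A = {1,2}, B = {3,4}: U_A = 0, exact two-sided p = 1/3
  mw <- mann_whitney_pc(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  # identical samples are exchangeable: p = 1
  expect_equal(mann_whitney_pc(c(5, 6, 7), c(5, 6, 7))$p, 1)
  # fully tied data
  expect_equal(mann_whitney_pc(rep(2, 4), rep(2, 5))$p, 1)

  # U_A + U_B = n_a * n_b
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    Ua <- mann_whitney_pc(a, b)$U
    Ub <- mann_whitney_pc(b, a)$U
    expect_equal(Ua + Ub, length(a) * length(b))
  }

  # the normal approximation stays within 0.02 of the exact p at n = 10+10
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10, 0.8)
  exact <- mann_whitney_pc(a, b)          # pooled 20 -> exact path
  r <- rank(c(a, b))
  # force the large-sample path by replicating the configuration via the
  # normal formula directly
  U <- exact$U; mu <- 50
  sig2 <- 10 * 10 * (21) / 12
  p_norm <- 2 * stats::pnorm(-abs((U - mu) / sqrt(sig2)))
  expect_lt(abs(p_norm - exact$p), 0.02)

  # agreement with the standard implementation on untied large samples
  set.seed(3)
  a2 <- rnorm(25); b2 <- rnorm(30, 0.3)
  ours <- mann_whitney_pc(a2, b2)
  ref <- stats::wilcox.test(a2, b2, exact = FALSE, correct = FALSE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("significance codes follow the star convention", {
  expect_equal(signif_code(c(0.2, 0.04, 0.009, 0.0005)),
               c("NS", "*", "**", "***"))
})
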