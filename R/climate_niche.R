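#' Extract environmental values at occurrence localities
#'
#' Reads every layer at the grid cell containing each locality. Localities
#' falling on masked (nodata) cells or outside the grid are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param env an `env_stack`.
#' @param occ an `occurrence_set`.
#' @return a data.frame (`trait_table`) with one row per retained locality,
#'   one column per layer, plus a `species` column; attributes `n_dropped`.
#' @export
extract_values <- function(env, occ) {
  xy <- as.matrix(as.data.frame(occ)[, c("x_km", "y_km")])
  cells <- cell_at(env, xy)
  ok <- !is.na(cells) & !env$nodata_mask[ifelse(is.na(cells), 1L, cells)]
  if (!any(ok))
    stop("all localities fall on nodata cells", call. = FALSE)
  vals <- as.data.frame(env_matrix(env, cells[ok]))
  vals$species <- attr(occ, "species_id")
  structure(vals, n_dropped = sum(!ok),
            class = c("trait_table", "data.frame"))
}

#' Per-species summary of a trait table
#'
#' Collapses locality-level environmental values to one value per species
#' and layer — the per-species trait used by phylogenetic-signal tests.
#'
#' @param tt a `trait_table` (or several row-bound together).
#' @param statistic `"mean"` (default) or `"median"`.
#' @return matrix, species x layers.
#' @export
species_summary <- function(tt, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  f <- if (statistic == "mean") mean else stats::median
  layers <- setdiff(names(tt), "species")
  sp <- unique(tt$species)
  out <- matrix(NA_real_, length(sp), length(layers),
                dimnames = list(sp, layers))
  for (s in sp) for (l in layers) out[s, l] <- f(tt[tt$species == s, l])
  out
}

#' Principal component comparison of a sister-species pair
#'
#' PCA on the pooled, standardized locality-level environmental values of
#' both species (correlation-matrix PCA: climate layers carry heterogeneous
#' units). Zero-variance layers are dropped with a warning. Scores keep
#' their species labels so component-wise two-sample tests can follow.
#'
#' @param tt_a,tt_b `trait_table`s of the two species.
#' @return list with `loadings` (layers x components), `scores`
#'   (localities x components), `species` (per score row), `pct_variance`.
#' @export
pair_pca <- function(tt_a, tt_b) {
  layers <- intersect(setdiff(names(tt_a), "species"),
                      setdiff(names(tt_b), "species"))
  X <- rbind(as.matrix(tt_a[, layers, drop = FALSE]),
             as.matrix(tt_b[, layers, drop = FALSE]))
  species <- c(tt_a$species, tt_b$species)
  if (nrow(X) < 3L) stop("need at least 3 pooled localities", call. = FALSE)
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance layer(s): ",
            paste(layers[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 informative layers", call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(loadings = p$rotation, scores = p$x, species = species,
       pct_variance = pct)
}

#' Mann-Whitney U test on principal component scores
#'
#' Two-sided rank test of a location shift between two species' scores on
#' one component. With pooled sample size <= 20 the exact permutation null
#' is enumerated; above that, the tie-corrected normal approximation is
#' used. Returns the U statistic of the first group.
#'
#' @param scores_a,scores_b numeric score vectors of the two species.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_pc <- function(scores_a, scores_b) {
  na <- length(scores_a); nb <- length(scores_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(scores_a, scores_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (all(pooled == pooled[1L]))
    return(list(U = U, p = 1, method = "degenerate"))
  if (na + nb <= 20L) {
    combs <- utils::combn(na + nb, na)
    Us <- apply(combs, 2L, function(ix) sum(r[ix])) - na * (na + 1) / 2
    mid <- na * nb / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-12)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    n <- na + nb
    sig2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
    z <- (U - mu) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

#' Significance code for a p-value
#'
#' Standard star convention: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `NS` otherwise.
#'
#' @param p numeric p-value(s).
#' @return character vector of codes.
#' @export
signif_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' PCA + Mann-Whitney summary for one species pair
#'
#' Convenience wrapper producing the PC1-PC3 significance codes reported in
#' pair tables.
#'
#' @param tt_a,tt_b `trait_table`s of the two species.
#' @param n_components number of leading components to test (default 3).
#' @return data.frame with one row per component: `component`, `U`, `p`,
#'   `code`, `pct_variance`.
#' @export
pair_pca_tests <- function(tt_a, tt_b, n_components = 3L) {
  res <- pair_pca(tt_a, tt_b)
  k <- min(n_components, ncol(res$scores))
  ia <- res$species == res$species[1L]
  out <- lapply(seq_len(k), function(j) {
    mw <- mann_whitney_pc(res$scores[ia, j], res$scores[!ia, j])
    data.frame(component = paste0("PC", j), U = mw$U, p = mw$p,
               code = signif_code(mw$p), pct_variance = res$pct_variance[j])
  })
  do.call(rbind, out)
}
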