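#' Normalize a non-negative suitability grid to a probability surface
#'
#' @param raw numeric vector/matrix of non-negative suitabilities, or a
#'   `niche_model` (whose `raw` surface is already normalized).
#' @return numeric vector summing to 1.
#' @export
normalize_surface <- function(raw) {
  if (inherits(raw, "niche_model")) raw <- raw$raw
  raw <- as.numeric(raw)
  if (any(raw < 0)) stop("suitabilities must be non-negative", call. = FALSE)
  s <- sum(raw)
  if (s <= 0) stop("all-zero surface cannot be normalized", call. = FALSE)
  raw / s
}

check_geometry <- function(p, q) {
  if (length(p) != length(q))
    stop("surfaces must share the same grid geometry", call. = FALSE)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p_i - q_i|)` over cells of two normalized suitability
#' surfaces; 0 means disjoint niches, 1 identical niches.
#'
#' @param p,q probability surfaces (vectors summing to 1, or `niche_model`s).
#' @return D in [0, 1].
#' @export
schoener_D <- function(p, q) {
  p <- normalize_surface(p); q <- normalize_surface(q)
  check_geometry(p, q)
  1 - 0.5 * sum(abs(p - q))
}

#' Hellinger-based I niche overlap
#'
#' `I = 1 - 0.5 * sum((sqrt(p_i) - sqrt(q_i))^2)`, i.e. one minus half the
#' squared Hellinger distance; always at least as large as D.
#'
#' @param p,q probability surfaces (vectors summing to 1, or `niche_model`s).
#' @return I in [0, 1].
#' @export
hellinger_I <- function(p, q) {
  p <- normalize_surface(p); q <- normalize_surface(q)
  check_geometry(p, q)
  1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)
}

overlap_stats <- function(p, q) {
  c(D = schoener_D(p, q), I = hellinger_I(p, q))
}

#' Default settings for models used inside randomization tests
#'
#' @param kinds feature kinds.
#' @param reg_multiplier L1 penalty multiplier.
#' @param max_iter optimizer iteration cap.
#' @param tol optimizer tolerance.
#' @param fallback_min_points species with fewer distinct presence cells
#'   than this use the uniform-over-range fallback surface instead of a
#'   fitted model (the rare-species rule).
#' @param buffer_radius_km radius used for fallback ranges and backgrounds.
#' @return a settings list.
#' @export
model_settings <- function(kinds = c("linear", "quadratic"),
                           reg_multiplier = 1, max_iter = 200L, tol = 1e-6,
                           fallback_min_points = 5L, buffer_radius_km = 20) {
  list(kinds = kinds, reg_multiplier = reg_multiplier, max_iter = max_iter,
       tol = tol, fallback_min_points = fallback_min_points,
       buffer_radius_km = buffer_radius_km)
}

# One suitability surface for a species: fitted model, or the uniform range
# fallback when there are too few distinct presence cells.
species_surface <- function(features, occ, settings = model_settings()) {
  env <- features$env
  cells <- presence_cells(features, occ)
  if (length(unique(cells)) < settings$fallback_min_points) {
    occ2 <- if (inherits(occ, "occurrence_set")) occ else
      occurrence_set("pseudo", cell_centers(env, cells))
    return(range_fallback_surface(
      buffer_range(occ2, settings$buffer_radius_km), env))
  }
  fit_maxent(features, cells, reg_multiplier = settings$reg_multiplier,
             max_iter = settings$max_iter, tol = settings$tol)
}

randomization_result <- function(test, observed, null_values, p, code,
                                 direction = NA_character_, extra = list()) {
  structure(c(list(test = test, observed = observed,
                   null_values = null_values, p = p, code = code,
                   direction = direction), extra),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> %s test (%d reps)\n", x$test,
              length(x$null_values$D)))
  for (m in c("D", "I"))
    cat(sprintf("  %s = %.3f  p = %.4g  %s\n", m, x$observed[[m]],
                x$p[[m]], x$code[[m]]))
  if (!is.na(x$direction)) cat("  direction:", x$direction, "\n")
  invisible(x)
}

#' Niche identity (equivalency) test
#'
#' Tests whether two species' niches are identical: the observed D and I
#' between their suitability surfaces are compared against a null built by
#' pooling the occurrence localities, randomly re-partitioning them into
#' the original sample sizes (without replacement), and refitting both
#' models. The test is one-tailed low: observed overlap smaller than the
#' null rejects niche identity. The null is invariant to the labeling of
#' the two species (the pooled set is put in canonical coordinate order and
#' the smaller group is drawn first).
#'
#' @param occ_a,occ_b `occurrence_set`s of the two species.
#' @param env an `env_stack`.
#' @param settings a [model_settings()] list.
#' @param n_reps pseudoreplicates (study setting 100).
#' @param seed RNG seed.
#' @param features optional prebuilt `feature_set` (saves rebuilding).
#' @return a `randomization_result` with per-metric pseudo-p
#'   `(1 + #(null <= obs)) / (n_reps + 1)` and significance codes.
#' @export
identity_test <- function(occ_a, occ_b, env, settings = model_settings(),
                          n_reps = 100L, seed = 1L, features = NULL) {
  if (is.null(features)) features <- build_features(env, settings$kinds)
  pa <- presence_cells(features, occ_a)
  pb <- presence_cells(features, occ_b)
  if (length(pa) + length(pb) < 4L)
    stop("pooled occurrence count too small for the identity test",
         call. = FALSE)
  obs <- overlap_stats(species_surface(features, occ_a, settings),
                       species_surface(features, occ_b, settings))
  pool <- sort(c(pa, pb))
  n_small <- min(length(pa), length(pb))
  local_seed(seed)
  null <- matrix(NA_real_, n_reps, 2L, dimnames = list(NULL, c("D", "I")))
  for (r in seq_len(n_reps)) {
    ix <- sample.int(length(pool), n_small)
    s1 <- species_surface(features, pool[ix], settings)
    s2 <- species_surface(features, pool[-ix], settings)
    null[r, ] <- overlap_stats(s1, s2)
  }
  p <- list(D = (1 + sum(null[, "D"] <= obs["D"])) / (n_reps + 1),
            I = (1 + sum(null[, "I"] <= obs["I"])) / (n_reps + 1))
  randomization_result(
    "identity", observed = as.list(obs),
    null_values = list(D = null[, "D"], I = null[, "I"]),
    p = p, code = list(D = signif_code(p$D), I = signif_code(p$I)))
}

#' Niche background similarity test (one direction)
#'
#' Tests whether the focal species' niche is more or less similar to its
#' sister's niche than expected from the sister's environmental background.
#' The null draws `n` cells (the sister's occurrence count) uniformly from
#' the sister's geographic range (buffer union of its localities), fits a
#' model on them, and records overlap with the focal model. Two-tailed at
#' the null's 2.5th/97.5th percentiles: `direction` is `"more"` above the
#' upper bound, `"less"` below the lower, `"NS"` otherwise (per metric),
#' with stars from the two-tailed pseudo-p. Run the test in both directions
#' per pair for the full published design.
#'
#' @param focal_occ `occurrence_set` of the focal species.
#' @param sister_occ `occurrence_set` of the sister species.
#' @param env an `env_stack`.
#' @param settings a [model_settings()] list; `buffer_radius_km` defines the
#'   background (cells within that distance of sister localities).
#' @param n_reps pseudoreplicates (study setting 100).
#' @param seed RNG seed.
#' @param features optional prebuilt `feature_set`.
#' @param sister_range optional precomputed `buffer_range` for the sister.
#' @return a `randomization_result`; `direction` and `code` are per-metric
#'   lists, `p` the two-tailed pseudo-p.
#' @export
background_test <- function(focal_occ, sister_occ, env,
                            settings = model_settings(), n_reps = 100L,
                            seed = 1L, features = NULL, sister_range = NULL) {
  if (is.null(features)) features <- build_features(env, settings$kinds)
  if (is.null(sister_range))
    sister_range <- buffer_range(sister_occ, settings$buffer_radius_km)
  focal_surface <- species_surface(features, focal_occ, settings)
  sister_surface <- species_surface(features, sister_occ, settings)
  obs <- overlap_stats(focal_surface, sister_surface)
  # cells available to the sister: unmasked cells inside its range
  bg_model <- range_fallback_surface(sister_range, env)
  bg_cells <- which(bg_model$raw > 0)
  n_sister <- length(presence_cells(features, sister_occ))
  if (length(bg_cells) < n_sister)
    stop("sister background smaller than its occurrence count", call. = FALSE)
  local_seed(seed)
  null <- matrix(NA_real_, n_reps, 2L, dimnames = list(NULL, c("D", "I")))
  for (r in seq_len(n_reps)) {
    draw <- sample(bg_cells, n_sister)
    null[r, ] <- overlap_stats(focal_surface,
                               species_surface(features, draw, settings))
  }
  res <- lapply(c(D = "D", I = "I"), function(m) {
    lo <- stats::quantile(null[, m], 0.025, names = FALSE)
    hi <- stats::quantile(null[, m], 0.975, names = FALSE)
    dir <- if (obs[m] > hi) "more" else if (obs[m] < lo) "less" else "NS"
    p_lo <- (1 + sum(null[, m] <= obs[m])) / (n_reps + 1)
    p_hi <- (1 + sum(null[, m] >= obs[m])) / (n_reps + 1)
    p2 <- min(1, 2 * min(p_lo, p_hi))
    list(direction = dir, p = p2,
         code = if (dir == "NS") "NS" else
           paste(dir, signif_code(p2)))
  })
  randomization_result(
    "background", observed = as.list(obs),
    null_values = list(D = null[, "D"], I = null[, "I"]),
    p = list(D = res$D$p, I = res$I$p),
    code = list(D = res$D$code, I = res$I$code),
    direction = NA_character_,
    extra = list(direction_by_metric = list(D = res$D$direction,
                                            I = res$I$direction),
                 focal = attr(focal_occ, "species_id"),
                 sister = attr(sister_occ, "species_id")))
}
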