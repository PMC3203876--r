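#' Sample background cells from an environmental stack
#'
#' Uniform random sample of unmasked cells (without replacement), capped at
#' `n`; used both for feature scaling and as the reference distribution for
#' AUC evaluation.
#'
#' @param env an `env_stack`.
#' @param n maximum number of cells (default 10000).
#' @param seed RNG seed.
#' @return integer vector of cell indices.
#' @export
sample_background <- function(env, n = 10000L, seed = 1L) {
  cells <- unmasked_cells(env)
  if (length(cells) <= n) return(cells)
  local_seed(seed)
  sort(sample(cells, n))
}

#' Build a linear + quadratic feature set over an environmental stack
#'
#' Features are min-max scaled per layer on the background cells (so scaled
#' values lie in [0, 1] there); quadratic features are squares of the scaled
#' linear ones. Constant layers are dropped with a warning. The full-grid
#' feature matrix is precomputed once so repeated model fits are cheap.
#'
#' @param env an `env_stack`.
#' @param kinds subset of `c("linear", "quadratic")`.
#' @param background_cells cell indices used for scaling (default: all
#'   unmasked cells).
#' @return a `feature_set`: list with `F` (cells x features), `defs`
#'   (data.frame layer/kind), `scaling`, `support` (unmasked cell indices),
#'   `background`, and the originating `env`.
#' @export
build_features <- function(env, kinds = c("linear", "quadratic"),
                           background_cells = NULL) {
  kinds <- match.arg(kinds, c("linear", "quadratic"), several.ok = TRUE)
  if (is.null(background_cells)) background_cells <- unmasked_cells(env)
  if (length(background_cells) == 0L)
    stop("background must be non-empty", call. = FALSE)
  E <- env_matrix(env)
  lo <- apply(E[background_cells, , drop = FALSE], 2L, min)
  hi <- apply(E[background_cells, , drop = FALSE], 2L, max)
  keep <- hi > lo
  if (!all(keep))
    warning("dropping constant layer(s): ",
            paste(names(env$layers)[!keep], collapse = ", "))
  lay <- names(env$layers)[keep]
  S <- sweep(sweep(E[, keep, drop = FALSE], 2L, lo[keep], `-`),
             2L, (hi - lo)[keep], `/`)
  Fs <- NULL
  defs <- NULL
  if ("linear" %in% kinds && length(lay)) {
    Fs <- S
    defs <- data.frame(layer = lay, kind = "linear")
  }
  if ("quadratic" %in% kinds && length(lay)) {
    Fs <- cbind(Fs, S^2)
    defs <- rbind(defs, data.frame(layer = lay, kind = "quadratic"))
  }
  if (is.null(Fs) || ncol(Fs) == 0L) {
    Fs <- matrix(0, n_cells(env), 0L)
    defs <- data.frame(layer = character(0), kind = character(0))
  }
  colnames(Fs) <- paste(defs$layer, defs$kind, sep = ".")
  structure(
    list(F = Fs, defs = defs,
         scaling = data.frame(layer = lay, min = lo[keep], max = hi[keep]),
         support = unmasked_cells(env), background = background_cells,
         env = env),
    class = "feature_set")
}

presence_cells <- function(features, presences) {
  if (inherits(presences, "occurrence_set")) {
    xy <- as.matrix(as.data.frame(presences)[, c("x_km", "y_km")])
    cells <- cell_at(features$env, xy)
    cells <- cells[!is.na(cells) & !features$env$nodata_mask[cells]]
    if (length(cells) == 0L)
      stop("no presence falls on a data cell", call. = FALSE)
    cells
  } else as.integer(presences)
}

#' Fit a minimal maximum-entropy suitability model
#'
#' Finds the exponential-family distribution over the study-area cells that
#' is closest to uniform subject to resembling the presence localities:
#' weights `lambda` minimize the convex objective
#' \deqn{-\frac1m \sum_{i\in pres} \lambda^T f_i + \log\sum_{cells} e^{\lambda^T f} + \sum_j \beta_j |\lambda_j|}
#' with per-feature L1 penalties `beta_j = reg_multiplier * s_j / sqrt(m)`
#' (`s_j` the background SD of feature j, `m` the presence count). The raw
#' suitability surface is the fitted probability distribution, normalized to
#' sum to 1 over unmasked cells. Optimization is monotone proximal gradient
#' descent with backtracking; `converged` is `FALSE` if `max_iter` is hit
#' before the step tolerance.
#'
#' @param features a `feature_set`.
#' @param presences an `occurrence_set` or integer cell indices; at least 2
#'   distinct presence cells required.
#' @param reg_multiplier multiplier on the default L1 penalty (study value 1).
#' @param max_iter iteration cap (study setting 500).
#' @param tol stopping tolerance on the step max-norm.
#' @param feature_cols optional integer/logical selection of feature columns
#'   (used by the jackknife).
#' @param trace if `TRUE`, record the objective value after every iteration
#'   in `objective_trace` (it is non-increasing by construction).
#' @return a `niche_model`: list with `lambda`, `raw` (full-grid vector
#'   summing to 1 over unmasked cells, 0 elsewhere), `logistic` (raw rescaled
#'   to max 1, display only), `training_gain`, `objective`, `converged`,
#'   `presence_cells`.
#' @export
fit_maxent <- function(features, presences, reg_multiplier = 1,
                       max_iter = 500L, tol = 1e-6, feature_cols = NULL,
                       trace = FALSE) {
  pres <- presence_cells(features, presences)
  if (length(unique(pres)) < 2L)
    stop("model-fallback: need >= 2 distinct presence cells; ",
         "use range_fallback_surface()", call. = FALSE)
  sup <- features$support
  Fall <- features$F
  if (!is.null(feature_cols)) Fall <- Fall[, feature_cols, drop = FALSE]
  J <- ncol(Fall)
  m <- length(pres)
  N <- length(sup)
  if (J == 0L) {
    raw <- numeric(n_cells(features$env))
    raw[sup] <- 1 / N
    return(structure(list(lambda = numeric(0), raw = raw,
                          logistic = raw / max(raw), training_gain = 0,
                          objective = log(N), converged = TRUE,
                          presence_cells = pres),
                     class = "niche_model"))
  }
  Fsup <- Fall[sup, , drop = FALSE]
  fbar <- colMeans(Fall[pres, , drop = FALSE])
  sj <- apply(Fall[features$background, , drop = FALSE], 2L, stats::sd)
  beta <- reg_multiplier * sj / sqrt(m)
  lambda <- numeric(J)
  smooth_obj <- function(l) {
    u <- Fsup %*% l
    mx <- max(u)
    -sum(fbar * l) + mx + log(sum(exp(u - mx)))
  }
  full_obj <- function(l) smooth_obj(l) + sum(beta * abs(l))
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  obj <- full_obj(lambda)
  obj_trace <- if (trace) obj else NULL
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- as.vector(Fsup %*% lambda)
    mx <- max(u)
    w <- exp(u - mx); w <- w / sum(w)
    g <- as.vector(crossprod(Fsup, w)) - fbar
    f0 <- -sum(fbar * lambda) + mx + log(sum(exp(u - mx)))
    repeat {
      cand <- soft(lambda - step * g, step * beta)
      dlt <- cand - lambda
      f1 <- smooth_obj(cand)
      if (f1 <= f0 + sum(g * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) { cand <- lambda; dlt <- dlt * 0; break }
    }
    lambda <- cand
    obj <- f1 + sum(beta * abs(lambda))
    if (trace) obj_trace <- c(obj_trace, obj)
    if (max(abs(dlt)) < tol) { converged <- TRUE; break }
    step <- step * 1.25
  }
  u <- as.vector(Fsup %*% lambda)
  p <- exp(u - max(u)); p <- p / sum(p)
  raw <- numeric(n_cells(features$env))
  raw[sup] <- p
  idx <- match(pres, sup)
  gain <- mean(log(p[idx])) - log(1 / N)
  structure(list(lambda = stats::setNames(lambda, colnames(Fall)), raw = raw,
                 logistic = raw / max(raw), training_gain = gain,
                 objective = obj, objective_trace = obj_trace,
                 converged = converged, presence_cells = pres),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("<niche_model> %d feature(s), training gain %.4f%s\n",
              length(x$lambda), x$training_gain,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Rank-based AUC from suitability scores
#'
#' Probability that a randomly chosen presence scores higher than a random
#' background cell, with ties counted one half.
#'
#' @param pres_scores,bg_scores numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_scores <- function(pres_scores, bg_scores) {
  n1 <- length(pres_scores); n0 <- length(bg_scores)
  if (n1 == 0L || n0 == 0L) stop("both score sets must be non-empty",
                                 call. = FALSE)
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a fitted model on test presences vs background
#' @param model a `niche_model`.
#' @param test_cells presence cell indices (or `occurrence_set`).
#' @param background_cells background cell indices.
#' @param features the `feature_set` (needed when `test_cells` is an
#'   `occurrence_set`).
#' @return AUC in [0, 1].
#' @export
model_auc <- function(model, test_cells, background_cells, features = NULL) {
  if (inherits(test_cells, "occurrence_set"))
    test_cells <- presence_cells(features, test_cells)
  auc_scores(model$raw[test_cells], model$raw[background_cells])
}

#' Bootstrap-replicated models with AUC evaluation
#'
#' Repeats the study's replication scheme: each replicate holds out a random
#' 25% (`1 - train_frac`) of presence cells as test data, fits the model on
#' a bootstrap resample (with replacement) of the remaining cells, and
#' scores AUC on the held-out cells against the background. The averaged
#' raw surface is renormalized to sum to 1. A per-cell SD surface across
#' replicates is produced only when the presence count is at least 8 (below
#' that the replicate spread is not meaningful).
#'
#' @param features a `feature_set`.
#' @param presences `occurrence_set` or cell indices.
#' @param n_reps replicates (study setting 100).
#' @param train_frac training fraction (study setting 0.75).
#' @param seed RNG seed.
#' @param ... passed to [fit_maxent()].
#' @return list `model` (averaged `niche_model`; `replicate_sd` attached or
#'   `NULL`) and `eval` (`auc`, `auc_sd`, `n_train`, `n_test`, `n_reps`).
#' @export
replicate_models <- function(features, presences, n_reps = 100L,
                             train_frac = 0.75, seed = 1L, ...) {
  pres <- presence_cells(features, presences)
  m <- length(pres)
  if (m < 2L)
    stop("model-fallback: need >= 2 presences; use range_fallback_surface()",
         call. = FALSE)
  local_seed(seed)
  n_test <- max(1L, floor((1 - train_frac) * m))
  n_train <- m - n_test
  if (n_train < 2L) { n_test <- m - 2L; n_train <- 2L }
  raw_sum <- 0; raw_sq <- 0
  aucs <- numeric(n_reps)
  last <- NULL
  for (r in seq_len(n_reps)) {
    test_ix <- if (n_test > 0L) sample.int(m, n_test) else integer(0)
    train_pool <- if (n_test > 0L) pres[-test_ix] else pres
    train <- sample(train_pool, length(train_pool), replace = TRUE)
    if (length(unique(train)) < 2L)
      train <- c(train, unique(pres)[1:2])
    fit <- fit_maxent(features, train, ...)
    raw_sum <- raw_sum + fit$raw
    raw_sq <- raw_sq + fit$raw^2
    aucs[r] <- if (n_test > 0L)
      auc_scores(fit$raw[pres[test_ix]], fit$raw[features$background]) else NA
    last <- fit
  }
  avg <- raw_sum / n_reps
  avg <- avg / sum(avg)
  sd_grid <- if (m >= 8L && n_reps > 1L)
    sqrt(pmax(0, raw_sq / n_reps - (raw_sum / n_reps)^2)) else NULL
  model <- last
  model$raw <- avg
  model$logistic <- avg / max(avg)
  model$replicate_sd <- sd_grid
  model$lambda <- NULL
  list(model = model,
       eval = list(auc = mean(aucs, na.rm = TRUE),
                   auc_sd = if (n_reps > 1L) stats::sd(aucs) else NA_real_,
                   n_train = n_train, n_test = n_test, n_reps = n_reps))
}

#' Jackknife variable contribution
#'
#' For every layer, refits the model using (a) only that layer's features
#' and (b) all features except that layer's, reporting training gains. The
#' layer with the highest gain-alone is the top contributing variable.
#'
#' @param features a `feature_set`.
#' @param presences `occurrence_set` or cell indices.
#' @param ... passed to [fit_maxent()].
#' @return data.frame: `layer`, `gain_alone`, `gain_without`; attribute
#'   `top_layer`.
#' @export
jackknife_contribution <- function(features, presences, ...) {
  layers <- unique(features$defs$layer)
  if (length(layers) < 2L) stop("need >= 2 layers", call. = FALSE)
  res <- lapply(layers, function(l) {
    alone <- fit_maxent(features, presences,
                        feature_cols = features$defs$layer == l, ...)
    without <- fit_maxent(features, presences,
                          feature_cols = features$defs$layer != l, ...)
    data.frame(layer = l, gain_alone = alone$training_gain,
               gain_without = without$training_gain)
  })
  out <- do.call(rbind, res)
  attr(out, "top_layer") <- out$layer[which.max(out$gain_alone)]
  out
}

#' Uniform suitability surface over a geographic range
#'
#' Fallback used when a species has too few unique localities to support a
#' fitted model: the raw surface is uniform over the unmasked cells whose
#' centres fall inside the buffer-union range and zero elsewhere.
#'
#' @param range a `buffer_range`.
#' @param env an `env_stack`.
#' @return a `niche_model` with uniform in-range raw surface.
#' @export
range_fallback_surface <- function(range, env) {
  cells <- unmasked_cells(env)
  ctr <- cell_centers(env, cells)
  inside <- rep(FALSE, length(cells))
  for (i in seq_len(nrow(range$centers))) {
    d2 <- (ctr[, 1L] - range$centers[i, 1L])^2 +
      (ctr[, 2L] - range$centers[i, 2L])^2
    inside <- inside | d2 <= range$radius_km^2
  }
  if (!any(inside))
    stop("no unmasked cell falls inside the range", call. = FALSE)
  raw <- numeric(n_cells(env))
  raw[cells[inside]] <- 1 / sum(inside)
  structure(list(lambda = NULL, raw = raw, logistic = raw / max(raw),
                 training_gain = NA_real_, objective = NA_real_,
                 converged = TRUE, presence_cells = integer(0)),
            class = "niche_model")
}
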