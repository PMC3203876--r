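# postorder list of internal nodes with their children, computed once per
# tree; kids is indexed by node id so inner loops avoid name lookups
tree_children <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(po$edge[, 1L])           # children visited before parents
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nn)
  sp <- split(tree$edge[, 2L], tree$edge[, 1L])
  kids[as.integer(names(sp))] <- sp
  list(order = parents, kids = kids, ntip = length(tree$tip.label), nn = nn)
}

# linear-parsimony cost given a precomputed traversal and values in tip order
l1_cost_core <- function(tc, x) {
  lo <- hi <- numeric(tc$nn)
  cost <- numeric(tc$nn)
  lo[seq_len(tc$ntip)] <- hi[seq_len(tc$ntip)] <- x
  for (nd in tc$order) {
    ch <- tc$kids[[nd]]
    if (length(ch) == 2L) {                  # binary fast path
      a <- ch[1L]; b <- ch[2L]
      l <- max(lo[a], lo[b]); h <- min(hi[a], hi[b])
      if (l <= h) { lo[nd] <- l; hi[nd] <- h; cost[nd] <- cost[a] + cost[b] }
      else { lo[nd] <- h; hi[nd] <- l; cost[nd] <- cost[a] + cost[b] + l - h }
    } else {
      e <- sort(c(lo[ch], hi[ch]))
      k <- length(ch)
      lo[nd] <- e[k]; hi[nd] <- e[k + 1L]
      m <- e[k]
      cost[nd] <- sum(cost[ch]) + sum(pmax(0, lo[ch] - m, m - hi[ch]))
    }
  }
  cost[tc$order[length(tc$order)]]
}

#' Minimal total change of a continuous character under linear parsimony
#'
#' The minimum of `sum(|state(child) - state(parent)|)` over all assignments
#' of states to internal nodes (branch lengths ignored: unit-change
#' parsimony). Computed exactly by bottom-up interval propagation: each node
#' carries the interval of optimal states; an internal node with k children
#' takes the median interval (k-th and (k+1)-th order statistics of the 2k
#' child interval endpoints), accumulating the distances from the child
#' intervals. Polytomies are handled by the same order-statistic rule.
#'
#' @param tree a `phylo` tree (branch lengths not used).
#' @param x numeric tip values, named by tip label or in tip order.
#' @return the minimal total change (>= 0).
#' @export
l1_parsimony_cost <- function(tree, x) {
  l1_cost_core(tree_children(tree), tip_values(tree, x))
}

tip_values <- function(tree, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("missing tip values: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[tree$tip.label]
  }
  if (length(x) != length(tree$tip.label))
    stop("need one value per tip", call. = FALSE)
  if (any(!is.finite(x))) stop("tip values must be finite", call. = FALSE)
  as.numeric(x)
}

#' Quantitative convergence index (QVI)
#'
#' A continuous-character analogue of one minus the retention index:
#' `QVI = (Obs - Min) / (Max - Min)` where `Obs` is the linear-parsimony
#' cost on the tree, `Min = max(x) - min(x)` (the cost on a perfectly
#' conforming tree) and `Max = sum(|x - median(x)|)` (the cost on a star
#' phylogeny). QVI is 0 when trait-similar species are sisters and 1 when
#' they are maximally dispersed over the tree. Constant traits — and trees
#' too small for `Max` to exceed `Min` (n <= 3) — return 0 by convention.
#'
#' @param tree a `phylo` tree.
#' @param x numeric tip values (named or in tip order).
#' @return QVI in [0, 1].
#' @export
qvi <- function(tree, x) {
  x <- tip_values(tree, x)
  qvi_core(tree_children(tree), x)
}

qvi_core <- function(tc, x) {
  mn <- max(x) - min(x)
  mx <- sum(abs(x - stats::median(x)))
  if (mx - mn <= 0) return(0)
  (l1_cost_core(tc, x) - mn) / (mx - mn)
}

#' QVI over a posterior tree sample with tip-randomization test
#'
#' Averages QVI over a sample of (posterior) trees and builds the null by
#' shuffling tip values — independently on each tree within each
#' randomization — and recording the across-tree mean QVI. Low observed
#' mean QVI relative to the null indicates phylogenetic signal; the default
#' calls significance when the observed mean falls below the 1st percentile
#' of the randomized means.
#'
#' @param posterior list of `phylo` trees (same tips); a single tree is
#'   accepted. Samples larger than `n_trees` are subsampled without
#'   replacement.
#' @param x numeric tip values named by tip label.
#' @param n_rand number of tip randomizations (study setting 1000).
#' @param n_trees maximum trees used (study setting 1000).
#' @param threshold null quantile below which the observed mean is called
#'   significant (default 0.01).
#' @param seed RNG seed.
#' @return list: `mean_QVI`, `mean_QVI_random`, `significant`, `null_means`,
#'   `threshold`.
#' @export
qvi_posterior_test <- function(posterior, x, n_rand = 1000L,
                               n_trees = 1000L, threshold = 0.01,
                               seed = 1L) {
  if (inherits(posterior, "phylo")) posterior <- list(posterior)
  if (length(posterior) == 0L) stop("empty posterior sample", call. = FALSE)
  local_seed(seed)
  if (length(posterior) > n_trees)
    posterior <- posterior[sample.int(length(posterior), n_trees)]
  tcs <- lapply(posterior, tree_children)
  xs <- lapply(posterior, tip_values, x = x)
  obs <- mean(mapply(qvi_core, tcs, xs))
  null_means <- vapply(seq_len(n_rand), function(r) {
    mean(mapply(function(tc, xv) qvi_core(tc, sample(xv)), tcs, xs))
  }, numeric(1))
  list(mean_QVI = obs, mean_QVI_random = mean(null_means),
       significant = obs < stats::quantile(null_means, threshold,
                                           names = FALSE),
       null_means = null_means, threshold = threshold)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]` where `MSE0` is the mean square of tip
#' values around the phylogenetically corrected mean, `MSE` the
#' generalized-least-squares mean square under the Brownian covariance `V`
#' of the tree, and the expectation is the Brownian value
#' `(tr(V) - n / sum(V^-1)) / (n - 1)`. K = 1 is the Brownian expectation;
#' K > 1 means stronger resemblance among relatives than Brownian motion
#' predicts, K < 1 weaker.
#'
#' @param tree a `phylo` tree with positive branch lengths, >= 4 tips.
#' @param x numeric tip values (named or in tip order).
#' @return K (>= 0).
#' @export
blomberg_k <- function(tree, x) {
  x <- tip_values(tree, x)
  if (length(x) < 4L) stop("need >= 4 tips", call. = FALSE)
  k_core(k_context(tree), x)
}

# precomputed Brownian covariance pieces, reused across randomizations
k_context <- function(tree) {
  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular Brownian covariance; check branch lengths", call. = FALSE))
  n <- nrow(V)
  list(Vi = Vi, sum_Vi = sum(Vi),
       expected = (sum(diag(V)) - n / sum(Vi)) / (n - 1), n = n)
}

k_core <- function(ctx, x) {
  ahat <- sum(ctx$Vi %*% x) / ctx$sum_Vi
  d <- x - ahat
  MSE0 <- sum(d^2) / (ctx$n - 1)
  MSE <- as.numeric(d %*% ctx$Vi %*% d) / (ctx$n - 1)
  (MSE0 / MSE) / ctx$expected
}

#' Randomization test for Blomberg's K
#'
#' Shuffles tip values across the tips and recomputes K;
#' `p = (1 + #(K_null >= K_obs)) / (n_rand + 1)`.
#'
#' @param tree a `phylo` tree.
#' @param x numeric tip values.
#' @param n_rand randomizations (study setting 999).
#' @param seed RNG seed.
#' @return list: `K`, `p`, `null_K`.
#' @export
k_randomization_test <- function(tree, x, n_rand = 999L, seed = 1L) {
  x <- tip_values(tree, x)
  ctx <- k_context(tree)
  obs <- k_core(ctx, x)
  local_seed(seed)
  null_K <- vapply(seq_len(n_rand), function(r)
    k_core(ctx, sample(x)), numeric(1))
  list(K = obs, p = (1 + sum(null_K >= obs)) / (n_rand + 1), null_K = null_K)
}

#' Per-variable phylogenetic signal table
#'
#' Runs the QVI posterior test and the K randomization test for every
#' column of a species-by-variable trait matrix, mirroring the layout of a
#' published signal table (mean QVI, mean randomized QVI, K, significance).
#'
#' @param posterior list of `phylo` trees (or one tree) for the QVI test.
#' @param traits numeric matrix, species x variables, rownames = tip labels.
#' @param tree single tree for K (default: first posterior tree).
#' @param n_rand randomizations for both tests.
#' @param seed RNG seed.
#' @param qvi_threshold passed to [qvi_posterior_test()].
#' @return data.frame: variable, mean_QVI, mean_QVI_random, qvi_significant,
#'   K, k_p, k_code.
#' @export
phylo_signal_table <- function(posterior, traits, tree = NULL,
                               n_rand = 999L, seed = 1L,
                               qvi_threshold = 0.01) {
  if (inherits(posterior, "phylo")) posterior <- list(posterior)
  if (is.null(tree)) tree <- posterior[[1L]]
  out <- lapply(seq_len(ncol(traits)), function(j) {
    x <- stats::setNames(traits[, j], rownames(traits))
    constant <- length(unique(x)) == 1L
    q <- qvi_posterior_test(posterior, x, n_rand = n_rand,
                            threshold = qvi_threshold, seed = seed + j)
    if (constant) {
      data.frame(variable = colnames(traits)[j], mean_QVI = 0,
                 mean_QVI_random = 0, qvi_significant = FALSE,
                 K = NA_real_, k_p = NA_real_, k_code = "constant")
    } else {
      k <- k_randomization_test(tree, x, n_rand = n_rand, seed = seed + j)
      data.frame(variable = colnames(traits)[j], mean_QVI = q$mean_QVI,
                 mean_QVI_random = q$mean_QVI_random,
                 qvi_significant = q$significant,
                 K = k$K, k_p = k$p, k_code = signif_code(k$p))
    }
  })
  do.call(rbind, out)
}
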