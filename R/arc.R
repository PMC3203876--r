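#' Pairwise niche overlap matrix across species
#'
#' @param surfaces named list of probability surfaces (or `niche_model`s),
#'   one per species, on a shared grid.
#' @param metric `"D"` (Schoener) or `"I"` (Hellinger-based).
#' @return symmetric species x species matrix with unit diagonal.
#' @export
overlap_matrix <- function(surfaces, metric = c("D", "I")) {
  metric <- match.arg(metric)
  if (length(surfaces) < 3L) stop("need >= 3 species", call. = FALSE)
  f <- if (metric == "D") schoener_D else hellinger_I
  ps <- lapply(surfaces, normalize_surface)
  n <- length(ps)
  M <- diag(1, n)
  dimnames(M) <- list(names(surfaces), names(surfaces))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    M[i, j] <- M[j, i] <- f(ps[[i]], ps[[j]])
  M
}

#' Mean between-clade niche overlap at every internal node
#'
#' For each internal node of the chronogram, averages the overlap matrix
#' over all tip pairs that straddle the node (one tip from each of two
#' different child clades; polytomies contribute all between-child-clade
#' pairs). With `weighting = "nested"`, each pair is down-weighted by
#' `0.5^(extra internal nodes on the paths from the node's children to the
#' tips)` so that deeply nested tips do not dominate (the standard
#' age-range-correlation correction); a weighted mean is returned.
#'
#' @param tree an ultrametric `phylo`; tips must appear in `M`.
#' @param M symmetric overlap matrix with species dimnames.
#' @param weighting `"unweighted"` (default) or `"nested"`.
#' @return data.frame: `node`, `age_ma`, `overlap` (one row per internal
#'   node, root included).
#' @export
node_overlap_profile <- function(tree, M,
                                 weighting = c("unweighted", "nested")) {
  weighting <- match.arg(weighting)
  missing_sp <- setdiff(tree$tip.label, rownames(M))
  if (length(missing_sp)) {
    warning("pruning tips absent from the overlap matrix: ",
            paste(missing_sp, collapse = ", "))
    tree <- ape::drop.tip(tree, missing_sp)
  }
  ntip <- length(tree$tip.label)
  ages <- ape::branching.times(tree)
  tc <- tree_children(tree)
  # tips below each node, and internal-node depth of each tip below it
  tipsets <- vector("list", ntip + tree$Nnode)
  depth <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) { tipsets[[i]] <- i; depth[[i]] <- 0L }
  rows <- NULL
  for (nd in tc$order) {
    ch <- tc$kids[[nd]]
    tipsets[[nd]] <- unlist(tipsets[ch])
    depth[[nd]] <- unlist(lapply(ch, function(c2) depth[[c2]] +
                                   as.integer(c2 > ntip)))
    num <- 0; den <- 0
    for (a in seq_along(ch)[-length(ch)]) for (b in (a + 1L):length(ch)) {
      ta <- tipsets[[ch[a]]]; tb <- tipsets[[ch[b]]]
      da <- depth[[ch[a]]];  db <- depth[[ch[b]]]
      w <- if (weighting == "nested")
        outer(0.5^da, 0.5^db) else matrix(1, length(ta), length(tb))
      sub <- M[tree$tip.label[ta], tree$tip.label[tb], drop = FALSE]
      num <- num + sum(w * sub); den <- den + sum(w)
    }
    rows <- rbind(rows, data.frame(node = nd,
                                   age_ma = unname(ages[as.character(nd)]),
                                   overlap = num / den))
  }
  rows
}

#' Ordinary least squares of overlap on node age
#' @param profile data.frame from [node_overlap_profile()] (columns
#'   `age_ma`, `overlap`), >= 2 nodes.
#' @return named numeric: `intercept`, `slope`.
#' @export
arc_regression <- function(profile) {
  if (nrow(profile) < 2L) stop("need >= 2 nodes", call. = FALSE)
  if (stats::var(profile$age_ma) == 0)
    stop("all node ages equal; slope undefined", call. = FALSE)
  co <- stats::coef(stats::lm(overlap ~ age_ma, data = profile))
  c(intercept = unname(co[1L]), slope = unname(co[2L]))
}

#' Monte-Carlo age-range-correlation test
#'
#' Fits the observed overlap-vs-age regression, then builds the null by
#' jointly permuting the species identities of the overlap matrix (rows and
#' columns together) and refitting. `f_greater` is the proportion of null
#' coefficients strictly greater than the observed one (ties excluded), for
#' the intercept and slope separately; it is reported as a frequency, not
#' converted to a two-sided p-value.
#'
#' @param tree an ultrametric `phylo`.
#' @param M symmetric overlap matrix with species dimnames.
#' @param n_sims permutations (study setting 1000).
#' @param seed RNG seed.
#' @param weighting passed to [node_overlap_profile()].
#' @return list: `intercept`, `slope`, `f_greater_intercept`,
#'   `f_greater_slope`, `n_sims`, `null_coefficients` (n_sims x 2).
#' @export
arc_mc_test <- function(tree, M, n_sims = 1000L, seed = 1L,
                        weighting = "unweighted") {
  obs <- arc_regression(node_overlap_profile(tree, M, weighting))
  sp <- rownames(M)
  local_seed(seed)
  null <- matrix(NA_real_, n_sims, 2L,
                 dimnames = list(NULL, c("intercept", "slope")))
  for (s in seq_len(n_sims)) {
    perm <- sample(sp)
    Mp <- M
    dimnames(Mp) <- list(perm, perm)
    null[s, ] <- arc_regression(node_overlap_profile(tree, Mp, weighting))
  }
  list(intercept = obs["intercept"], slope = obs["slope"],
       f_greater_intercept = mean(null[, "intercept"] > obs["intercept"]),
       f_greater_slope = mean(null[, "slope"] > obs["slope"]),
       n_sims = n_sims, null_coefficients = null)
}
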