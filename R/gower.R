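#' Gower distance on a mixed binary/continuous trait matrix
#'
#' Pairwise species dissimilarity for mixed data: the mean over traits of the
#' per-trait contribution, which is the range-normalised absolute difference
#' \eqn{|x_{it} - x_{jt}| / (\max_t - \min_t)} for a continuous trait and the
#' mismatch indicator for a binary trait.  Ranges are taken over the full
#' regional pool (as stored in the [trait_matrix()]), so distances of a
#' subset of species are consistent with the pool.  All traits carry equal
#' weight by default; with `group_weights = TRUE` each binary state group
#' (a single ecological trait dummy-expanded into several columns) receives
#' total weight 1, shared equally among its columns, so multi-state traits
#' are not implicitly up-weighted.
#'
#' @param traits a [trait_matrix()].
#' @param group_weights logical; if `TRUE`, down-weight columns of the same
#'   binary state group so each group sums to weight 1.  Default `FALSE`
#'   (flat per-column weights).
#' @return a symmetric species x species numeric matrix of dissimilarities
#'   in `[0, 1]`, zero on the diagonal, with species labels as dimnames.
#' @examples
#' tm <- generate_trait_matrix(n_species = 6, seed = 1)
#' d <- gower_distance(tm)
#' range(d)
#' @references Gower, J.C. (1971) A general coefficient of similarity and
#'   some of its properties. Biometrics 27, 857-871.
#' @export
gower_distance <- function(traits, group_weights = FALSE) {
  if (!inherits(traits, "trait_matrix")) {
    stop("'traits' must be a trait_matrix", call. = FALSE)
  }
  X <- traits$values
  n <- nrow(X)
  p <- ncol(X)
  w <- rep(1, p)
  if (group_weights) {
    for (g in unique(traits$groups[!is.na(traits$groups)])) {
      idx <- which(!is.na(traits$groups) & traits$groups == g)
      w[idx] <- 1 / length(idx)
    }
  }
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (j in seq_len(p)) {
    xj <- X[, j]
    if (traits$kinds[j] == "continuous") {
      rng <- traits$ranges["max", j] - traits$ranges["min", j]
      if (rng <= 0) {
        stop(sprintf("continuous trait '%s' has zero range over the pool",
                     colnames(X)[j]), call. = FALSE)
      }
      contrib <- abs(outer(xj, xj, "-")) / rng
    } else {
      contrib <- outer(xj, xj, "!=") * 1
    }
    D <- D + w[j] * contrib
  }
  D / sum(w)
}
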