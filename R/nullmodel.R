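#' Richness-controlled null expectation of FD
#'
#' The null model behind "predicted FD": communities of exactly `S` species
#' are assembled uniformly at random, without replacement, from the full
#' regional pool, and their FD on the shared regional dendrogram is
#' averaged.  Deviations of observed FD below this expectation at matched
#' richness indicate trait convergence (environmental filtering); deviations
#' above it indicate divergence (limiting similarity).
#'
#' @param tree regional [build_dendrogram()] tree.
#' @param S community richness, `1 <= S <=` pool size.
#' @param n_reps number of random assemblages (default 500).
#' @param seed integer seed.
#' @param exact if `TRUE`, enumerate all `choose(N, S)` subsets instead of
#'   sampling (feasible for small pools); `n_reps` and `seed` are then
#'   ignored and `sd` is the exact population standard deviation.
#' @return a one-row data.frame with columns `S`, `predicted_fd`, `sd`,
#'   `n_reps`.
#' @examples
#' tr <- build_dendrogram(gower_distance(generate_trait_matrix(n_species = 8,
#'   seed = 5)))
#' predicted_fd(tr, S = 3, n_reps = 200, seed = 1)
#' predicted_fd(tr, S = 3, exact = TRUE)
#' @export
predicted_fd <- function(tree, S, n_reps = 500L, seed = 1L, exact = FALSE) {
  N <- tree$n
  S <- as.integer(S)
  if (S < 1L) stop("'S' must be at least 1", call. = FALSE)
  if (S > N) {
    stop(sprintf("richness S = %d exceeds the pool size %d", S, N),
         call. = FALSE)
  }
  if (exact) {
    sub <- utils::combn(N, S)
    vals <- apply(sub, 2, function(idx) {
      pres <- integer(N); pres[idx] <- 1L
      fd(tree, pres)
    })
    m <- ncol(sub)
    return(data.frame(S = S, predicted_fd = mean(vals),
                      sd = sqrt(mean((vals - mean(vals))^2)),
                      n_reps = m))
  }
  if (n_reps < 1L) stop("'n_reps' must be at least 1", call. = FALSE)
  if (S == N) {
    # only one subset exists: the pool itself
    return(data.frame(S = S, predicted_fd = fd(tree, tree$labels), sd = 0,
                      n_reps = as.integer(n_reps)))
  }
  vals <- with_seed(seed, fd_of_random_subsets(tree, S, n_reps))
  data.frame(S = S, predicted_fd = mean(vals), sd = stats::sd(vals),
             n_reps = as.integer(n_reps))
}

# FD of m uniform random S-subsets, vectorised over subsets.
# Assumes the RNG is already positioned (callers seed it).
fd_of_random_subsets <- function(tree, S, m) {
  if (S == 1L) return(numeric(m))
  P <- random_subsets(tree$n, S, m)
  counts <- tree$edge_leaves %*% P              # edges x m
  include <- counts > 0L & counts < S
  as.vector(crossprod(include, tree$edge_length))
}

#' Null-model predicted FD for every site of a community table
#'
#' Computes the Monte-Carlo null expectation once per distinct richness
#' level and maps it back to sites, so all sites of equal richness share one
#' reference distribution, as in a richness-controlled null model.
#'
#' @param tree regional `functional_dendrogram`.
#' @param communities site x species presence matrix.
#' @param n_reps random assemblages per richness level (default 500).
#' @param seed integer seed.
#' @return a data.frame of class `null_fd_result` with columns `site`, `SR`,
#'   `predicted_fd`, `sd`, `n_reps`.
#' @examples
#' tm <- generate_trait_matrix(seed = 1)
#' tr <- build_dendrogram(gower_distance(tm))
#' cm <- generate_communities(tm, assembly_scenario("neutral", seed = 2))
#' head(null_model_fd(tr, cm, n_reps = 100, seed = 3))
#' @export
null_model_fd <- function(tree, communities, n_reps = 500L, seed = 1L) {
  P <- community_matrix(communities)
  SR <- rowSums(P)
  levels_S <- sort(unique(SR))
  per_level <- lapply(levels_S, function(s) {
    predicted_fd(tree, s, n_reps = n_reps,
                 seed = (seed + s) %% .Machine$integer.max)
  })
  ref <- do.call(rbind, per_level)
  i <- match(SR, ref$S)
  out <- data.frame(site = rownames(P), SR = as.integer(SR),
                    predicted_fd = ref$predicted_fd[i], sd = ref$sd[i],
                    n_reps = as.integer(n_reps), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("null_fd_result", class(out))
  out
}
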