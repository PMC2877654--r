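# Independent brute-force oracles: deliberately naive implementations used
# only to check the package's fast paths.

# Gower distance by an explicit per-pair, per-trait loop.
oracle_gower <- function(tm) {
  X <- tm$values
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (t in seq_len(ncol(X))) {
      if (tm$kinds[t] == "continuous") {
        rng <- tm$ranges["max", t] - tm$ranges["min", t]
        acc <- acc + abs(X[i, t] - X[j, t]) / rng
      } else {
        acc <- acc + as.numeric(X[i, t] != X[j, t])
      }
    }
    D[i, j] <- acc / ncol(X)
  }
  D
}

# UPGMA cophenetic matrix straight from the definition: at each step the
# inter-cluster distance is the mean over all original cross pairs
# (no Lance-Williams recurrence), ties broken lexicographically.
oracle_upgma_cophenetic <- function(D) {
  labs <- rownames(D)
  clusters <- lapply(labs, identity)
  C <- matrix(0, nrow(D), nrow(D), dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      d <- mean(D[clusters[[a]], clusters[[b]]])
      key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
      if (is.null(best) || d < best$d - 1e-12 ||
          (d <= best$d + 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(a = a, b = b, d = d, key = key)
      }
    }
    C[clusters[[best$a]], clusters[[best$b]]] <- best$d
    C[clusters[[best$b]], clusters[[best$a]]] <- best$d
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  C
}

# Subtree FD as a union of leaf-to-root edge paths minus the shared
# LCA-to-root path; uses only the merge table and heights.
oracle_fd <- function(tree, members) {
  n <- tree$n
  n_nodes <- n + (n - 1L)
  parent <- rep(NA_integer_, n_nodes)       # leaves 1..n, merges n+k
  hgt <- c(rep(0, n), tree$height)
  for (k in seq_len(n - 1L)) {
    for (cd in tree$merge[k, ]) {
      child <- if (cd < 0L) -cd else n + cd
      parent[child] <- n + k
    }
  }
  path_edges <- function(leaf) {
    edges <- character(0)
    node <- leaf
    while (!is.na(parent[node])) {
      edges <- c(edges, paste(node, parent[node]))
      node <- parent[node]
    }
    edges
  }
  edge_len <- function(e) {
    nd <- as.integer(strsplit(e, " ")[[1]])
    hgt[nd[2]] - hgt[nd[1]]
  }
  idx <- match(members, tree$labels)
  paths <- lapply(idx, path_edges)
  all_edges <- unique(unlist(paths))
  shared <- Reduce(intersect, paths)
  sum(vapply(setdiff(all_edges, shared), edge_len, numeric(1)))
}

# Small random mixed trait matrix (independent binary columns, no groups).
random_small_traits <- function(n, n_bin = 3, n_cont = 2, seed = 1) {
  set.seed(seed)
  vals <- cbind(
    matrix(rbinom(n * n_bin, 1, 0.5), n, n_bin),
    matrix(runif(n * n_cont), n, n_cont)
  )
  # guarantee non-zero range in continuous columns
  for (j in (n_bin + 1):(n_bin + n_cont)) {
    vals[1, j] <- 0; vals[2, j] <- 1
  }
  colnames(vals) <- c(paste0("b", seq_len(n_bin)), paste0("c", seq_len(n_cont)))
  rownames(vals) <- sprintf("sp%02d", seq_len(n))
  trait_matrix(vals, c(rep("binary", n_bin), rep("continuous", n_cont)))
}

# Cophenetic matrix of a random ultrametric tree built by sequential random
# merging at strictly increasing heights.
random_ultrametric_cophenetic <- function(n, seed = 1) {
  set.seed(seed)
  labs <- sprintf("sp%02d", seq_len(n))
  clusters <- lapply(seq_len(n), function(i) labs[i])
  C <- matrix(0, n, n, dimnames = list(labs, labs))
  h <- 0
  while (length(clusters) > 1L) {
    h <- h + runif(1, 0.05, 0.2)
    ab <- sample.int(length(clusters), 2L)
    C[clusters[[ab[1]]], clusters[[ab[2]]]] <- 2 * h
    C[clusters[[ab[2]]], clusters[[ab[1]]]] <- 2 * h
    clusters[[ab[1]]] <- c(clusters[[ab[1]]], clusters[[ab[2]]])
    clusters[[ab[2]]] <- NULL
  }
  C
}
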