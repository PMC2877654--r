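#' Build a functional dendrogram by agglomerative clustering
#'
#' Hierarchical agglomeration of species under a named linkage rule, recorded
#' as an ultrametric tree: each merge of two clusters at average (or single,
#' complete, WPGMA, Ward) inter-cluster distance `d` places the new node at
#' height `d / 2`, so the cophenetic distance between two leaves equals the
#' inter-cluster distance at their merge and every leaf sits at depth equal
#' to the root height.  Ties in the minimal inter-cluster distance are broken
#' by the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its alphabetically first member), which makes trees
#' bit-reproducible across platforms.
#'
#' Ward linkage operates on squared distances (Lance-Williams update) with
#' merge heights rescaled to the distance scale (square root, halved) so its
#' output is ultrametric like the other candidates; it is included as a
#' selection candidate for [select_clustering()].
#'
#' @param dist symmetric dissimilarity matrix (or `dist`), e.g. from
#'   [gower_distance()].
#' @param linkage one of `"UPGMA"`, `"WPGMA"`, `"single"`, `"complete"`,
#'   `"Ward"`.
#' @return an object of class `functional_dendrogram` with elements `merge`
#'   and `height` (hclust-style merge table; heights on the ultrametric
#'   leaf-depth scale, i.e. half the merge distance), `labels`, `order`,
#'   `linkage`, and precomputed `edge_length` / `edge_leaves` (per-branch
#'   lengths and leaf incidence) used by [fd()].
#' @examples
#' d <- gower_distance(generate_trait_matrix(n_species = 8, seed = 2))
#' tr <- build_dendrogram(d, "UPGMA")
#' tr
#' @seealso [fd()], [select_clustering()], [stats::hclust()]
#' @export
build_dendrogram <- function(dist,
                             linkage = c("UPGMA", "WPGMA", "single",
                                         "complete", "Ward")) {
  linkage <- match.arg(linkage)
  D0 <- as_distance_matrix(dist)
  n <- nrow(D0)
  if (n < 2L) stop("need at least 2 species to build a dendrogram", call. = FALSE)
  labels <- rownames(D0)

  cur <- if (linkage == "Ward") D0^2 else D0
  diag(cur) <- Inf
  size <- rep(1L, n)
  code <- -seq_len(n)             # hclust convention: negatives are leaves
  minlab <- labels                # alphabetically first member per cluster
  node_height <- rep(0, n)        # current height of each active cluster top

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))  # leaf indices per active cluster

  edge_length <- numeric(2L * (n - 1L))
  edge_leaves <- matrix(FALSE, 2L * (n - 1L), n)
  e <- 0L

  for (k in seq_len(n - 1L)) {
    m <- nrow(cur)
    dmin <- min(cur[upper.tri(cur)])
    idx <- which(upper.tri(cur) & cur <= dmin + 1e-12, arr.ind = TRUE)
    if (nrow(idx) > 1L) {
      lo <- pmin(minlab[idx[, 1L]], minlab[idx[, 2L]])
      hi <- pmax(minlab[idx[, 1L]], minlab[idx[, 2L]])
      idx <- idx[order(lo, hi)[1L], , drop = FALSE]
    }
    a <- idx[1L, 1L]; b <- idx[1L, 2L]
    h <- if (linkage == "Ward") sqrt(dmin) / 2 else dmin / 2
    if (k > 1L) h <- max(h, height[k - 1L])   # numerical monotonicity guard

    merge[k, ] <- sort(c(code[a], code[b]))
    height[k] <- h

    for (child in c(a, b)) {
      e <- e + 1L
      edge_length[e] <- h - node_height[child]
      edge_leaves[e, members[[child]]] <- TRUE
    }

    drest <- setdiff(seq_len(m), c(a, b))
    if (length(drest)) {
      dik <- cur[a, drest]; djk <- cur[b, drest]
      ni <- size[a]; nj <- size[b]; nk <- size[drest]
      newd <- switch(linkage,
        single   = pmin(dik, djk),
        complete = pmax(dik, djk),
        UPGMA    = (ni * dik + nj * djk) / (ni + nj),
        WPGMA    = (dik + djk) / 2,
        Ward     = ((ni + nk) * dik + (nj + nk) * djk - nk * cur[a, b]) /
                   (ni + nj + nk)
      )
      cur[a, drest] <- newd
      cur[drest, a] <- newd
    }
    size[a] <- size[a] + size[b]
    code[a] <- k
    minlab[a] <- min(minlab[a], minlab[b])
    node_height[a] <- h
    members[[a]] <- c(members[[a]], members[[b]])

    keep <- setdiff(seq_len(m), b)
    cur <- cur[keep, keep, drop = FALSE]
    size <- size[keep]; code <- code[keep]; minlab <- minlab[keep]
    node_height <- node_height[keep]; members <- members[keep]
  }

  tree <- structure(
    list(merge = merge, height = height, labels = labels,
         linkage = linkage, n = n,
         edge_length = edge_length, edge_leaves = edge_leaves),
    class = "functional_dendrogram"
  )
  tree$order <- leaf_order(tree)
  tree
}

# Leaf plotting order by depth-first traversal of the merge table.
leaf_order <- function(tree) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(tree$merge[node, 1L]), walk(tree$merge[node, 2L]))
  }
  walk(nrow(tree$merge))
}

#' @export
print.functional_dendrogram <- function(x, ...) {
  cat(sprintf("Functional dendrogram: %d species, %s linkage\n", x$n, x$linkage))
  cat(sprintf("Root height %.4f, total branch length %.4f\n",
              x$height[length(x$height)], sum(x$edge_length)))
  invisible(x)
}

#' @export
as.hclust.functional_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = 2 * x$height, order = x$order,
         labels = x$labels, method = x$linkage, call = match.call(),
         dist.method = "user"),
    class = "hclust"
  )
}

#' Convert a functional dendrogram to an ape phylogeny
#'
#' Branch lengths are on the ultrametric height scale, so the patristic
#' distance between two leaves in the returned `phylo` equals the cophenetic
#' distance of the dendrogram.
#'
#' @param x a `functional_dendrogram`.
#' @param ... unused.
#' @return an [ape::phylo] object.
#' @export
as.phylo.functional_dendrogram <- function(x, ...) {
  ape::as.phylo(as.hclust(x))
}

#' @export
plot.functional_dendrogram <- function(x, ...) {
  plot(as.hclust(x), ...)
}

#' Cophenetic distances implied by a functional dendrogram
#'
#' The tree-implied distance between two leaves: twice the height of their
#' lowest common ancestor.
#'
#' @param x a `functional_dendrogram`.
#' @return a symmetric labelled matrix.
#' @export
cophenetic.functional_dendrogram <- function(x) {
  n <- x$n
  C <- matrix(0, n, n, dimnames = list(x$labels, x$labels))
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    side <- lapply(x$merge[k, ], function(cd) {
      if (cd < 0L) -cd else members[[cd]]
    })
    C[side[[1L]], side[[2L]]] <- 2 * x$height[k]
    C[side[[2L]], side[[1L]]] <- 2 * x$height[k]
    members[[k]] <- c(side[[1L]], side[[2L]])
  }
  C
}

#' Select the clustering method that best preserves the distance matrix
#'
#' Builds one candidate dendrogram per linkage rule and scores each by the
#' summed squared discrepancy between the input dissimilarities and the
#' tree's cophenetic (ultrametric) distances,
#' \eqn{\sum_{i<j} (d_{ij} - c_{ij})^2}.  The linkage with the minimal
#' criterion is selected; exact ties go to the earlier entry of the fixed
#' preference order UPGMA, WPGMA, complete, single, Ward.
#'
#' @param dist symmetric dissimilarity matrix (or `dist`).
#' @param candidates character vector of linkage names to score.
#' @return an object of class `method_selection`: list with `candidates`,
#'   `criterion` (named numeric), `selected`, and `trees` (the candidate
#'   `functional_dendrogram`s, so the winner need not be rebuilt).
#' @examples
#' d <- gower_distance(generate_trait_matrix(n_species = 10, seed = 3))
#' sel <- select_clustering(d)
#' sel$selected
#' @export
select_clustering <- function(dist,
                              candidates = c("UPGMA", "WPGMA", "complete",
                                             "single", "Ward")) {
  D <- as_distance_matrix(dist)
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  pref <- c("UPGMA", "WPGMA", "complete", "single", "Ward")
  candidates <- match.arg(candidates, pref, several.ok = TRUE)
  ut <- upper.tri(D)
  trees <- lapply(candidates, function(l) build_dendrogram(D, l))
  names(trees) <- candidates
  crit <- vapply(trees, function(tr) {
    sum((D[ut] - cophenetic(tr)[rownames(D), colnames(D)][ut])^2)
  }, numeric(1))
  ord <- order(match(candidates, pref))
  near_min <- crit <= min(crit) + 1e-12      # numerical ties share the min
  best <- ord[which(near_min[ord])[1L]]
  structure(
    list(candidates = candidates, criterion = crit,
         selected = candidates[best], trees = trees),
    class = "method_selection"
  )
}

#' @export
print.method_selection <- function(x, ...) {
  cat("Clustering-method selection (cophenetic least-squares criterion)\n")
  tab <- data.frame(linkage = x$candidates,
                    criterion = signif(x$criterion, 6),
                    selected = ifelse(x$candidates == x$selected, "*", ""))
  print(tab, row.names = FALSE)
  invisible(x)
}
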