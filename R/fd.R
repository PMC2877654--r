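#' Functional diversity of a community on the regional dendrogram
#'
#' FD in the dendrogram-based sense: the total branch length of the minimal
#' subtree of the regional functional dendrogram that connects the species
#' present in a community, truncated at their lowest common ancestor (the
#' stem above the LCA does not count).  One regional tree, built from the
#' full species pool, is shared by all communities, which guarantees set
#' monotonicity (adding a species can never decrease FD) and makes the
#' richness-controlled null model coherent.  A single-species community has
#' FD 0 by convention; the full pool attains the total branch length of the
#' tree.
#'
#' @param tree a [build_dendrogram()] result over the regional pool.
#' @param members community membership: a character vector of species labels,
#'   or a logical/0-1 vector over the tree's leaves (in leaf-label order).
#' @return a single non-negative number.
#' @examples
#' tm <- generate_trait_matrix(n_species = 8, seed = 4)
#' tr <- build_dendrogram(gower_distance(tm), "UPGMA")
#' fd(tr, species_pool(tr)[1:3])
#' @references Petchey, O.L. & Gaston, K.J. (2002) Functional diversity (FD),
#'   species richness and community composition. Ecology Letters 5, 402-411.
#' @export
fd <- function(tree, members) {
  pres <- as_presence(tree, members)
  S <- sum(pres)
  counts <- as.vector(tree$edge_leaves %*% pres)
  sum(tree$edge_length[counts > 0L & counts < S])
}

#' Species labels of a functional dendrogram
#' @param tree a `functional_dendrogram`.
#' @return character vector of leaf labels.
#' @export
species_pool <- function(tree) tree$labels

as_presence <- function(tree, members) {
  n <- tree$n
  if (is.character(members)) {
    if (length(members) == 0L) stop("community is empty", call. = FALSE)
    unknown <- setdiff(members, tree$labels)
    if (length(unknown)) {
      stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    pres <- as.integer(tree$labels %in% members)
  } else if (is.logical(members) || is.numeric(members)) {
    if (length(members) != n) {
      stop("presence vector length must equal the number of leaves", call. = FALSE)
    }
    if (is.numeric(members) && !all(members %in% c(0, 1))) {
      stop("presence vector must be 0/1", call. = FALSE)
    }
    pres <- as.integer(as.logical(members))
    if (sum(pres) == 0L) stop("community is empty", call. = FALSE)
  } else {
    stop("'members' must be species labels or a presence vector", call. = FALSE)
  }
  pres
}

#' Observed FD for every site of a community table
#'
#' @param tree regional `functional_dendrogram`.
#' @param communities a site x species presence matrix (a
#'   [generate_communities()] result or any 0/1 matrix with species column
#'   names matching the tree's leaves).
#' @return a data.frame with columns `site`, `SR`, `FD`.
#' @export
fd_table <- function(tree, communities) {
  P <- community_matrix(communities)
  miss <- setdiff(tree$labels, colnames(P))
  extra <- setdiff(colnames(P), tree$labels)
  if (length(miss) || length(extra)) {
    stop("species sets of tree and community table differ; ",
         "only in tree: {", paste(miss, collapse = ", "), "}; ",
         "only in table: {", paste(extra, collapse = ", "), "}",
         call. = FALSE)
  }
  P <- P[, tree$labels, drop = FALSE]
  S <- rowSums(P)
  if (any(S < 1)) stop("every site must contain at least one species", call. = FALSE)
  counts <- tree$edge_leaves %*% t(P)          # edges x sites
  include <- counts > 0L & sweep(counts, 2, S, "<")
  fdv <- as.vector(crossprod(include, tree$edge_length))
  data.frame(site = rownames(P), SR = as.integer(S), FD = fdv,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Coerce community input to a plain 0/1 site x species matrix.
community_matrix <- function(communities) {
  P <- if (inherits(communities, "community_table")) unclass(communities)
       else communities
  P <- as.matrix(P)
  if (!all(P %in% c(0, 1))) stop("community table must be 0/1", call. = FALSE)
  if (is.null(colnames(P))) stop("community table needs species column names",
                                 call. = FALSE)
  if (is.null(rownames(P))) rownames(P) <- sprintf("site%02d", seq_len(nrow(P)))
  storage.mode(P) <- "integer"
  P
}
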