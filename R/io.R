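# Plain-text readers and writers for the pipeline's tables and trees.
# All tables are tab-separated with a header row and a leading label column;
# trait-kind metadata travels in a sidecar file (trait, kind, group per line).

#' Write / read a trait matrix with its sidecar metadata file
#'
#' @param traits a [trait_matrix()].
#' @param file path of the tab-separated value table (species in rows).
#' @param meta_file path of the sidecar metadata file; defaults to
#'   `<file>.meta`.
#' @return `write_trait_matrix` returns `file` invisibly;
#'   `read_trait_matrix` returns a [trait_matrix()].
#' @export
write_trait_matrix <- function(traits, file,
                               meta_file = paste0(file, ".meta")) {
  df <- data.frame(species = rownames(traits$values), traits$values,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(trait = colnames(traits$values), kind = traits$kinds,
                     group = ifelse(is.na(traits$groups), ".", traits$groups))
  utils::write.table(meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(file, meta_file = paste0(file, ".meta")) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE)
  meta <- utils::read.table(meta_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  ord <- match(colnames(values), meta$trait)
  if (any(is.na(ord))) stop("sidecar metadata does not cover all traits",
                            call. = FALSE)
  groups <- meta$group[ord]
  groups[groups == "."] <- NA_character_
  trait_matrix(values, meta$kind[ord], groups)
}

#' Write / read a site-by-species community table
#' @param communities 0/1 site x species matrix.
#' @param file path of the tab-separated table.
#' @return the path (writer, invisibly) or a `community_table` (reader).
#' @export
write_community_table <- function(communities, file) {
  P <- community_matrix(communities)
  df <- data.frame(site = rownames(P), P, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_community_table
#' @export
read_community_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE)
  P <- as.matrix(df[, -1, drop = FALSE])
  rownames(P) <- df[[1]]
  storage.mode(P) <- "integer"
  structure(P, class = c("community_table", class(P)))
}

#' Write / read a habitat table
#' @param habitat data.frame of habitat variables.
#' @param file path of the tab-separated table.
#' @return the path (writer, invisibly) or a `habitat_table` data.frame
#'   (reader).
#' @export
write_habitat_table <- function(habitat, file) {
  df <- data.frame(site = rownames(as.data.frame(habitat)),
                   as.data.frame(habitat), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_habitat_table
#' @export
read_habitat_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE)
  rownames(df) <- df[[1]]
  df <- df[, -1, drop = FALSE]
  class(df) <- c("habitat_table", class(df))
  df
}

#' Write a labelled square distance matrix
#' @param d symmetric labelled matrix.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(d, file) {
  d <- as_distance_matrix(d)
  df <- data.frame(species = rownames(d), d, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write / read a functional dendrogram in Newick format
#'
#' Branch lengths are on the ultrametric height scale used by [fd()]
#' (cophenetic distance = patristic distance).
#'
#' @param tree a `functional_dendrogram`.
#' @param file Newick file path.
#' @return the path (writer, invisibly); the reader returns a
#'   `functional_dendrogram` rebuilt by UPGMA from the tree's cophenetic
#'   distances (exact for ultrametric input).
#' @export
write_dendrogram <- function(tree, file) {
  ape::write.tree(as.phylo.functional_dendrogram(tree), file)
  invisible(file)
}

#' @rdname write_dendrogram
#' @export
read_dendrogram <- function(file) {
  phy <- ape::read.tree(file)
  coph <- ape::cophenetic.phylo(phy)
  build_dendrogram(coph[sort(rownames(coph)), sort(rownames(coph))], "UPGMA")
}
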