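#' Construct a species-by-trait matrix with mixed trait kinds
#'
#' The trait matrix is the basis of the functional space: one row per species
#' of the regional pool, one column per morphological trait.  Binary columns
#' code exclusive character states (e.g. oral-disc shapes dummy-expanded into
#' one column per state); continuous columns hold measurements such as the
#' number of keratodont rows.  Trait ranges used for Gower normalisation are
#' computed here, over the full pool.
#'
#' @param values numeric matrix, species x traits, with row and column names.
#' @param kinds character vector, one of `"binary"` or `"continuous"` per
#'   trait column.
#' @param groups optional character vector of group labels per trait, marking
#'   which binary columns expand the same exclusive ecological trait
#'   (`NA` for ungrouped columns).  Used only by the optional per-group Gower
#'   weighting; ignored otherwise.
#' @return an object of class `trait_matrix`: a list with elements `values`,
#'   `kinds`, `groups` and `ranges` (per-trait observed min/max).
#' @examples
#' vals <- cbind(shapeA = c(1, 0, 0), shapeB = c(0, 1, 1),
#'               rows = c(2, 5, 8))
#' rownames(vals) <- paste0("sp", 1:3)
#' tm <- trait_matrix(vals, kinds = c("binary", "binary", "continuous"))
#' tm
#' @seealso [gower_distance()], [generate_trait_matrix()]
#' @export
trait_matrix <- function(values, kinds, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 2L) {
    stop("a trait matrix needs at least 2 species", call. = FALSE)
  }
  if (any(is.na(values))) {
    stop("missing trait values are not supported; measure or impute first",
         call. = FALSE)
  }
  kinds <- match.arg(kinds, c("binary", "continuous"), several.ok = TRUE)
  if (length(kinds) != ncol(values)) {
    stop("'kinds' must give one kind per trait column", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("sp%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("trait%02d", seq_len(ncol(values)))
  }
  for (j in which(kinds == "binary")) {
    if (!all(values[, j] %in% c(0, 1))) {
      stop(sprintf("binary trait '%s' contains values outside {0, 1}",
                   colnames(values)[j]), call. = FALSE)
    }
  }
  if (is.null(groups)) groups <- rep(NA_character_, ncol(values))
  if (length(groups) != ncol(values)) {
    stop("'groups' must give one label (or NA) per trait column", call. = FALSE)
  }
  ranges <- rbind(min = apply(values, 2, min), max = apply(values, 2, max))
  structure(
    list(values = values, kinds = kinds, groups = as.character(groups),
         ranges = ranges),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  nb <- sum(x$kinds == "binary")
  nc <- sum(x$kinds == "continuous")
  cat(sprintf("Trait matrix: %d species x %d traits (%d binary, %d continuous)\n",
              nrow(x$values), ncol(x$values), nb, nc))
  grp <- x$groups[!is.na(x$groups)]
  if (length(grp)) {
    cat("Binary state groups:",
        paste(sprintf("%s (%d)", unique(grp), table(grp)[unique(grp)]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

species_labels <- function(traits) rownames(traits$values)
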