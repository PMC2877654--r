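# Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Sets the RNG to a reproducible state, runs `expr`, and restores the
#' caller's RNG state on exit, so seeded generators never perturb the global
#' random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive named per-stage seeds from one root seed (all < 2^31).
derive_seeds <- function(seed, stages) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
    names(s) <- stages
    s
  })
}

# Moment-based sample skewness (g1).
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Validate a square symmetric dissimilarity matrix; returns it with labels.
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stop("distance input must be a square numeric matrix or 'dist' object",
         call. = FALSE)
  }
  if (any(is.na(d))) stop("distance matrix contains missing values", call. = FALSE)
  if (any(d < 0)) stop("distance matrix contains negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix has non-zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("sp%02d", seq_len(nrow(d)))
  }
  d
}

# Uniform random subsets of size S from n, as an n x m 0/1 matrix.
random_subsets <- function(n, S, m) {
  idx <- vapply(seq_len(m), function(i) sample.int(n, S), integer(S))
  P <- matrix(0L, n, m)
  P[cbind(as.vector(idx), rep(seq_len(m), each = S))] <- 1L
  P
}
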