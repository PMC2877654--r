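#' Polynomial-regression test for functional redundancy
#'
#' Fits ordinary least squares of FD on species richness, linear
#' (`FD ~ SR`) and quadratic (`FD ~ SR + SR^2`, raw powers), and assesses
#' the quadratic term.  A significantly negative quadratic coefficient means
#' the FD-SR curve flattens at high richness: added species contribute
#' progressively less unique trait variety, i.e. functional redundancy.
#'
#' @param fd_values per-site observed FD.
#' @param SR per-site species richness.
#' @param alpha significance level for the redundancy verdict (default 0.05).
#' @return an object of class `fd_redundancy`: list with the two [lm] fits
#'   (`linear`, `quadratic`), a coefficient table for the quadratic model,
#'   per-model `r_squared`, `f_statistic` (value, df1, df2, p per model),
#'   `quadratic_term` (estimate, se, t, p), and `verdict`
#'   (`"redundancy"` / `"no evidence"`).
#' @examples
#' SR <- rep(2:18, length.out = 29)
#' fdv <- SR / (5 + SR) + rnorm(29, sd = 0.01)
#' redundancy_test(fdv, SR)
#' @export
redundancy_test <- function(fd_values, SR, alpha = 0.05) {
  if (length(fd_values) != length(SR)) {
    stop("'fd_values' and 'SR' must have equal length", call. = FALSE)
  }
  n <- length(SR)
  if (n < 4L) stop("need at least 4 sites", call. = FALSE)
  if (stats::var(SR) == 0) stop("SR is constant across sites; fit impossible",
                                call. = FALSE)
  dat <- data.frame(FD = fd_values, SR = SR)
  lin <- stats::lm(FD ~ SR, data = dat)
  quad <- stats::lm(FD ~ SR + I(SR^2), data = dat)

  fstat <- function(fit) {
    s <- summary(fit)
    f <- s$fstatistic
    c(value = unname(f["value"]), df1 = unname(f["numdf"]),
      df2 = unname(f["dendf"]),
      p = stats::pf(f["value"], f["numdf"], f["dendf"], lower.tail = FALSE))
  }
  qs <- summary(quad)$coefficients
  quad_term <- c(estimate = qs["I(SR^2)", 1], se = qs["I(SR^2)", 2],
                 t = qs["I(SR^2)", 3], p = qs["I(SR^2)", 4])
  verdict <- if (quad_term["estimate"] < 0 && quad_term["p"] < alpha) {
    "redundancy"
  } else {
    "no evidence"
  }
  structure(
    list(linear = lin, quadratic = quad,
         coefficients = qs,
         r_squared = c(linear = summary(lin)$r.squared,
                       quadratic = summary(quad)$r.squared),
         f_statistic = rbind(linear = fstat(lin), quadratic = fstat(quad)),
         quadratic_term = quad_term, alpha = alpha, n = n,
         verdict = verdict),
    class = "fd_redundancy"
  )
}

#' @export
print.fd_redundancy <- function(x, digits = 4, ...) {
  cat("Functional-redundancy test (polynomial regression of FD on SR)\n")
  f <- x$f_statistic
  cat(sprintf("  linear:    F(%d,%d) = %.4g, R^2 = %.3f\n",
              f["linear", "df1"], f["linear", "df2"], f["linear", "value"],
              x$r_squared["linear"]))
  cat(sprintf("  quadratic: F(%d,%d) = %.4g, R^2 = %.3f\n",
              f["quadratic", "df1"], f["quadratic", "df2"],
              f["quadratic", "value"], x$r_squared["quadratic"]))
  q <- x$quadratic_term
  cat(sprintf("  SR^2 term: %.4g (SE %.3g), t = %.3f, p = %.4g\n",
              q["estimate"], q["se"], q["t"], q["p"]))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
summary.fd_redundancy <- function(object, ...) {
  print(object)
  cat("\nQuadratic model coefficients:\n")
  stats::printCoefmat(object$coefficients)
  invisible(object)
}
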