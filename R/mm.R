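#' Grouped Michaelis-Menten comparison of observed and predicted FD
#'
#' Both FD-richness curves are saturating, so observed and null-predicted FD
#' are compared by a joint nonlinear least-squares fit of the
#' Michaelis-Menten form
#' \deqn{FD(S) = (F_{max} + \delta_{Fmax} g)\, S / ((K + \delta_K g) + S)}
#' where `g = 1` for observed points and 0 for predicted ones --- the
#' nonlinear analogue of an ANCOVA with a group factor.  `Fmax` is the
#' asymptotic maximum FD and `K` the richness at half-maximal FD; the group
#' offsets \eqn{\delta_{Fmax}, \delta_K} measure how the observed curve
#' departs from the null curve.  Each offset is tested with
#' `t = delta / SE(delta)` on `n - 4` degrees of freedom, one-sided against
#' the alternative that the observed parameter is *lower* than the
#' predicted one (trait convergence depresses the FD ceiling; divergence is
#' never inferred from this test).
#'
#' Starting values are data-driven (`Fmax0 = 1.1 * max(FD)`,
#' `K0 = median(SR)`, offsets 0); on failure a 3 x 3 restart grid
#' (`Fmax0 x {0.5, 1, 2}`, `K0 x {0.5, 1, 2}`) is tried with
#' Levenberg-Marquardt refinement, and an explicit error is raised if no
#' start converges.
#'
#' @param fd_values numeric FD values for all points of both groups.
#' @param SR species richness per point (positive).
#' @param group factor or character with levels `"observed"` and
#'   `"predicted"`.
#' @return an object of class `mm_comparison`: list with `estimates` (named
#'   vector: `Fmax_pred`, `K_pred`, `dFmax`, `dK`, `Fmax_obs`, `K_obs`),
#'   `se`, `t`, `p_one_sided` for the offsets, `df`, `n`, `side`, the
#'   underlying `fit`, and the data.
#' @examples
#' S <- rep(2:18, length.out = 29)
#' obs <- 1.11 * S / (5 + S) + rnorm(29, sd = 0.02)
#' pre <- 1.21 * S / (5 + S) + rnorm(29, sd = 0.02)
#' cmp <- fit_mm_grouped(c(obs, pre), c(S, S),
#'                       rep(c("observed", "predicted"), each = 29))
#' cmp
#' @export
fit_mm_grouped <- function(fd_values, SR, group) {
  if (length(fd_values) != length(SR) || length(SR) != length(group)) {
    stop("'fd_values', 'SR' and 'group' must have equal length", call. = FALSE)
  }
  if (any(SR <= 0)) stop("'SR' must be positive", call. = FALSE)
  group <- as.character(group)
  bad <- setdiff(unique(group), c("observed", "predicted"))
  if (length(bad)) {
    stop("unknown group labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(c("observed", "predicted") %in% group)) {
    stop("both groups ('observed' and 'predicted') must be non-empty",
         call. = FALSE)
  }
  dat <- data.frame(FD = fd_values, S = SR,
                    g = as.numeric(group == "observed"))
  n <- nrow(dat)
  if (n < 5L) stop("need more points than parameters (4)", call. = FALSE)

  Fmax0 <- 1.1 * max(dat$FD)
  K0 <- stats::median(dat$S)
  form <- FD ~ (Fmax + dFmax * g) * S / ((K + dK * g) + S)
  fit <- NULL
  for (fs in c(1, 0.5, 2)) {
    for (ks in c(1, 0.5, 2)) {
      start <- list(Fmax = Fmax0 * fs, K = K0 * ks, dFmax = 0, dK = 0)
      fit <- tryCatch(stats::nls(form, data = dat, start = start),
                      error = function(e) NULL)
      if (is.null(fit)) {
        fit <- tryCatch(minpack.lm::nlsLM(form, data = dat, start = start),
                        error = function(e) NULL)
      }
      if (!is.null(fit)) break
    }
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("Michaelis-Menten fit did not converge from any start in the ",
         "restart grid", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  df <- n - 4L
  t_off <- est[c("dFmax", "dK")] / se[c("dFmax", "dK")]
  p_one <- stats::pt(t_off, df)   # alternative: observed < predicted
  estimates <- c(Fmax_pred = unname(est["Fmax"]), K_pred = unname(est["K"]),
                 dFmax = unname(est["dFmax"]), dK = unname(est["dK"]),
                 Fmax_obs = unname(est["Fmax"] + est["dFmax"]),
                 K_obs = unname(est["K"] + est["dK"]))
  structure(
    list(estimates = estimates,
         se = c(Fmax = unname(se["Fmax"]), K = unname(se["K"]),
                dFmax = unname(se["dFmax"]), dK = unname(se["dK"])),
         t = t_off, p_one_sided = p_one, df = df, n = n,
         side = "observed < predicted", fit = fit, data = dat),
    class = "mm_comparison"
  )
}

#' @export
print.mm_comparison <- function(x, ...) {
  e <- x$estimates
  cat("Grouped Michaelis-Menten comparison of FD-SR curves\n")
  cat(sprintf("  predicted: Fmax = %.3f (SE %.3f), K = %.3f (SE %.3f)\n",
              e["Fmax_pred"], x$se["Fmax"], e["K_pred"], x$se["K"]))
  cat(sprintf("  observed:  Fmax = %.3f, K = %.3f\n",
              e["Fmax_obs"], e["K_obs"]))
  cat(sprintf("  dFmax = %.4f (SE %.4f), t = %.3f, df = %d, one-sided p = %.4g\n",
              e["dFmax"], x$se["dFmax"], x$t["dFmax"], x$df,
              x$p_one_sided["dFmax"]))
  cat(sprintf("  dK    = %.4f (SE %.4f), t = %.3f, df = %d, one-sided p = %.4g\n",
              e["dK"], x$se["dK"], x$t["dK"], x$df, x$p_one_sided["dK"]))
  cat("  alternative:", x$side, "\n")
  invisible(x)
}

#' @export
coef.mm_comparison <- function(object, ...) object$estimates

#' @export
summary.mm_comparison <- function(object, ...) {
  print(object)
  cat("\nJoint nls fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' Fitted MM curves at given richness values
#' @param object an `mm_comparison`.
#' @param SR richness values at which to evaluate both curves.
#' @param ... unused.
#' @return data.frame with `SR`, `observed`, `predicted`.
#' @export
predict.mm_comparison <- function(object, SR = sort(unique(object$data$S)),
                                  ...) {
  e <- object$estimates
  data.frame(SR = SR,
             observed = e["Fmax_obs"] * SR / (e["K_obs"] + SR),
             predicted = e["Fmax_pred"] * SR / (e["K_pred"] + SR))
}

#' @export
plot.mm_comparison <- function(x, ...) {
  d <- x$data
  plot(d$S, d$FD, pch = ifelse(d$g == 1, 16, 1),
       xlab = "Species richness", ylab = "FD", ...)
  s <- seq(min(d$S), max(d$S), length.out = 200)
  pr <- predict(x, s)
  lines(s, pr$observed, lty = 1)
  lines(s, pr$predicted, lty = 2)
  legend("bottomright", c("observed", "predicted"), pch = c(16, 1),
         lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Low-FD verdict from a Michaelis-Menten comparison
#'
#' Declares "low FD" --- the signature of environmental filtering --- when
#' the one-sided test on the maximum-FD offset rejects at `alpha`
#' (observed asymptote significantly below the null-model asymptote).
#' A positive or null offset yields "not low"; the half-saturation (K)
#' contrast is reported alongside but high FD (competition) is never
#' asserted from this test.
#'
#' @param mm an [fit_mm_grouped()] result.
#' @param alpha significance level (default 0.05).
#' @return an object of class `fd_verdict`: list with `verdict`
#'   (`"low FD"` / `"not low"`), `alpha`, and the `Fmax` and `K` contrasts
#'   (estimate, t, df, one-sided p).
#' @export
low_fd_verdict <- function(mm, alpha = 0.05) {
  if (!inherits(mm, "mm_comparison")) {
    stop("'mm' must be an mm_comparison", call. = FALSE)
  }
  reject <- is.finite(mm$p_one_sided["dFmax"]) &&
    mm$estimates["dFmax"] < 0 && mm$p_one_sided["dFmax"] < alpha
  structure(
    list(verdict = if (reject) "low FD" else "not low",
         alpha = alpha,
         fmax_contrast = c(estimate = unname(mm$estimates["dFmax"]),
                           t = unname(mm$t["dFmax"]), df = mm$df,
                           p = unname(mm$p_one_sided["dFmax"])),
         k_contrast = c(estimate = unname(mm$estimates["dK"]),
                        t = unname(mm$t["dK"]), df = mm$df,
                        p = unname(mm$p_one_sided["dK"]))),
    class = "fd_verdict"
  )
}

#' @export
print.fd_verdict <- function(x, ...) {
  cat(sprintf("FD verdict: %s (alpha = %g)\n", x$verdict, x$alpha))
  cat(sprintf("  Fmax contrast: %.4f, t = %.3f, df = %d, p = %.4g\n",
              x$fmax_contrast["estimate"], x$fmax_contrast["t"],
              x$fmax_contrast["df"], x$fmax_contrast["p"]))
  cat(sprintf("  K contrast:    %.4f, t = %.3f, df = %d, p = %.4g\n",
              x$k_contrast["estimate"], x$k_contrast["t"],
              x$k_contrast["df"], x$k_contrast["p"]))
  invisible(x)
}
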