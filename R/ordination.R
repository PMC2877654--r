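#' Box-Cox power transformation with profile-likelihood lambda
#'
#' \eqn{y(\lambda) = (x^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0} and
#' \eqn{\log x} at \eqn{\lambda = 0}, with \eqn{\lambda} chosen by
#' maximising the normal profile log-likelihood over a grid.  Inputs must be
#' positive; when zeros are present, an offset of half the smallest positive
#' value is added first and reported.  Used to tame skewed habitat
#' variables before PCA so single outliers do not dominate the ordination.
#'
#' @param values numeric vector, non-negative.
#' @param lambda_grid candidate exponents (default `seq(-2, 2, by = 0.1)`).
#' @return list with `transformed`, `lambda`, `offset`, and the profile
#'   `loglik` over the grid.
#' @examples
#' x <- exp(rnorm(100))
#' boxcox_transform(x)$lambda   # near 0 for log-normal data
#' @export
boxcox_transform <- function(values, lambda_grid = seq(-2, 2, by = 0.1)) {
  if (any(is.na(values))) stop("missing values not supported", call. = FALSE)
  if (any(values < 0)) stop("Box-Cox requires non-negative input", call. = FALSE)
  if (stats::var(values) == 0) stop("constant input cannot be transformed",
                                    call. = FALSE)
  offset <- 0
  if (any(values == 0)) {
    pos <- values[values > 0]
    offset <- min(pos) / 2
    values <- values + offset
  }
  n <- length(values)
  logx <- log(values)
  ll <- vapply(lambda_grid, function(lam) {
    y <- if (abs(lam) < 1e-12) logx else (values^lam - 1) / lam
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (lam - 1) * sum(logx)
  }, numeric(1))
  lam <- lambda_grid[which.max(ll)]
  y <- if (abs(lam) < 1e-12) logx else (values^lam - 1) / lam
  list(transformed = y, lambda = lam, offset = offset,
       loglik = stats::setNames(ll, lambda_grid))
}

#' Screen and transform skewed habitat variables
#'
#' Applies [boxcox_transform()] to every variable whose absolute sample
#' skewness exceeds `skew_threshold` (a reproducible stand-in for visual
#' outlier screening); other variables pass through unchanged.
#'
#' @param habitat data.frame of numeric habitat variables.
#' @param skew_threshold absolute skewness above which a variable is
#'   transformed (default 1).
#' @return list with `values` (transformed data.frame), `transformed`
#'   (names of affected variables), `lambda` and `offset` per affected
#'   variable.
#' @export
prepare_habitat <- function(habitat, skew_threshold = 1) {
  X <- as.data.frame(habitat)
  done <- character(); lambda <- numeric(); offset <- numeric()
  for (v in names(X)) {
    if (!is.numeric(X[[v]])) stop("habitat variables must be numeric",
                                  call. = FALSE)
    if (stats::var(X[[v]]) > 0 &&
        abs(sample_skewness(X[[v]])) > skew_threshold &&
        all(X[[v]] >= 0)) {
      bc <- boxcox_transform(X[[v]])
      X[[v]] <- bc$transformed
      done <- c(done, v)
      lambda <- c(lambda, bc$lambda); offset <- c(offset, bc$offset)
    }
  }
  list(values = X, transformed = done,
       lambda = stats::setNames(lambda, done),
       offset = stats::setNames(offset, done))
}

#' Correlation-matrix principal component analysis
#'
#' Centres and scales every variable to unit variance (i.e. works on the
#' correlation matrix, so variables of unequal units and variance contribute
#' equally) and eigendecomposes it.  Loadings are sign-fixed so the
#' largest-magnitude loading of each component is positive, a pure reporting
#' convention.
#'
#' @param habitat data.frame or matrix of numeric variables (sites x
#'   variables).
#' @return an object of class `habitat_pca`: list with `eigenvalues`,
#'   `proportion` (of total variance), `loadings` (variables x components),
#'   `scores` (sites x components), `center`, `scale`, `n_sites`.
#' @examples
#' tm <- generate_trait_matrix(seed = 1)
#' cm <- generate_communities(tm, assembly_scenario("neutral", seed = 2))
#' hb <- generate_habitat(cm, 0.8, seed = 3)
#' pca <- run_pca(hb)
#' pca$proportion[1:3]
#' @export
run_pca <- function(habitat) {
  X <- as.matrix(as.data.frame(habitat))
  if (!is.numeric(X)) stop("habitat variables must be numeric", call. = FALSE)
  if (any(is.na(X))) stop("habitat table contains missing values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant habitat variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  V <- eig$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- Z %*% V
  structure(
    list(eigenvalues = vals, proportion = vals / sum(vals),
         loadings = V, scores = scores,
         center = attr(Z, "scaled:center"), scale = attr(Z, "scaled:scale"),
         n_sites = nrow(X)),
    class = "habitat_pca"
  )
}

#' @export
print.habitat_pca <- function(x, n = 5, ...) {
  k <- min(n, length(x$eigenvalues))
  cat(sprintf("Correlation-matrix PCA: %d sites, %d variables\n",
              x$n_sites, nrow(x$loadings)))
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `proportion (%)` = 100 * x$proportion[1:k],
               `cumulative (%)` = 100 * cumsum(x$proportion)[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 2))
  invisible(x)
}

#' @export
plot.habitat_pca <- function(x, ...) {
  graphics::barplot(x$eigenvalues, names.arg = paste0("PC",
                    seq_along(x$eigenvalues)),
                    ylab = "Eigenvalue", las = 2, ...)
  bs <- broken_stick(length(x$eigenvalues)) * sum(x$eigenvalues)
  graphics::lines(seq_along(bs) * 1.2 - 0.5, bs, type = "b", pch = 4)
  invisible(x)
}

#' Bootstrapped-eigenvector significance test for PCA loadings
#'
#' Resamples sites with replacement, recomputes the correlation-matrix PCA
#' per resample, aligns bootstrap axes to the original ones (greedy matching
#' on absolute loading-vector congruence, with sign reflection to positive
#' congruence, since resampled axes may swap order or flip), and flags a
#' loading as significant when its empirical two-sided `(1 - alpha)`
#' percentile interval excludes zero.  Resamples in which a variable becomes
#' constant are redrawn and counted.
#'
#' @param habitat data.frame of numeric variables.
#' @param n_boot bootstrap replicates (>= 199; default 999).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed integer seed.
#' @return an object of class `pca_boot`: list with `flags` (logical
#'   variables x components), `lower`/`upper` percentile bounds,
#'   `original` loadings, `n_boot`, `alpha`, `n_redrawn`.
#' @references Peres-Neto, P.R., Jackson, D.A. & Somers, K.M. (2003) Giving
#'   meaningful interpretation to ordination axes. Ecology 84, 2347-2363.
#' @export
bootstrap_eigenvector_test <- function(habitat, n_boot = 999L, alpha = 0.05,
                                       seed = 1L) {
  if (n_boot < 199L) stop("'n_boot' must be at least 199", call. = FALSE)
  X <- as.matrix(as.data.frame(habitat))
  n <- nrow(X); p <- ncol(X)
  orig <- run_pca(X)
  V0 <- orig$loadings
  boot <- array(NA_real_, c(p, p, n_boot))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (all(apply(Xb, 2, stats::sd) > 0)) break
        n_redrawn <- n_redrawn + 1L
      }
      Vb <- eigen(stats::cor(Xb), symmetric = TRUE)$vectors
      boot[, , b] <- align_axes(Vb, V0)
    }
  })
  lower <- apply(boot, c(1, 2), stats::quantile, probs = alpha / 2)
  upper <- apply(boot, c(1, 2), stats::quantile, probs = 1 - alpha / 2)
  dimnames(lower) <- dimnames(upper) <- dimnames(V0)
  flags <- lower > 0 | upper < 0
  structure(
    list(flags = flags, lower = lower, upper = upper, original = V0,
         n_boot = as.integer(n_boot), alpha = alpha, n_redrawn = n_redrawn),
    class = "pca_boot"
  )
}

# Greedy matching of bootstrap eigenvectors to the original axes by maximal
# absolute congruence (dot product of unit vectors), with sign reflection.
align_axes <- function(Vb, V0) {
  p <- ncol(V0)
  G <- crossprod(Vb, V0)          # boot axis x original axis congruence
  out <- matrix(NA_real_, p, p)
  absG <- abs(G)
  for (step in seq_len(p)) {
    ij <- which(absG == max(absG), arr.ind = TRUE)[1, ]
    bi <- ij[1]; oi <- ij[2]
    out[, oi] <- Vb[, bi] * sign(G[bi, oi])
    absG[bi, ] <- -Inf
    absG[, oi] <- -Inf
  }
  out
}

#' @export
print.pca_boot <- function(x, n = 3, ...) {
  k <- min(n, ncol(x$flags))
  cat(sprintf("Bootstrapped-eigenvector test (%d resamples, alpha = %g)\n",
              x$n_boot, x$alpha))
  cat(sprintf("Significant loadings on PC1..PC%d:\n", k))
  for (c_ in seq_len(k)) {
    sig <- rownames(x$flags)[x$flags[, c_]]
    signs <- ifelse(x$original[sig, c_] > 0, "+", "-")
    cat(sprintf("  PC%d: %s\n", c_,
                if (length(sig)) paste0(sig, " (", signs, ")", collapse = ", ")
                else "none"))
  }
  if (x$n_redrawn > 0) cat("  degenerate resamples redrawn:", x$n_redrawn, "\n")
  invisible(x)
}

# Broken-stick expected proportions of variance for p components.
broken_stick <- function(p) {
  vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
}

#' Number of components to retain
#'
#' Automated scree decision by the broken-stick rule: retain the leading
#' run of components whose variance proportion exceeds the broken-stick
#' expectation \eqn{b_k = (1/p) \sum_{j=k}^{p} 1/j}.  A manual override
#' reproduces a visual scree choice.
#'
#' @param eigenvalues non-increasing eigenvalues (>= 2 of them).
#' @param override if given, return this count regardless.
#' @return integer number of components.
#' @examples
#' select_n_components(c(7, 3.2, 1.8, 0.5, 0.5, 0.5, 0.5))
#' select_n_components(rep(1, 14))          # 0: no structure
#' select_n_components(rep(1, 14), override = 3)
#' @export
select_n_components <- function(eigenvalues, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  p <- length(eigenvalues)
  if (p < 2L) stop("need at least 2 eigenvalues", call. = FALSE)
  prop <- eigenvalues / sum(eigenvalues)
  bs <- broken_stick(p)
  k <- 0L
  while (k < p && prop[k + 1L] > bs[k + 1L]) k <- k + 1L
  k
}

#' Regress species richness on retained principal components
#'
#' Multiple linear regression of SR on the retained component scores,
#' without interactions, followed by backward elimination: while any
#' component has `p >= threshold`, the worst is dropped and the model is
#' refitted, yielding the minimal adequate model.  The elimination trace
#' records every drop.
#'
#' @param scores sites x components score matrix (e.g. `run_pca(...)$scores`
#'   restricted to retained components).
#' @param SR per-site species richness.
#' @param threshold retention p-value threshold (default 0.05).
#' @return an object of class `sr_regression`: list with the final [lm]
#'   `fit`, `coefficients` table, `r_squared`, `f_statistic`, `retained`
#'   component names, and the `trace` of eliminations.
#' @export
regress_sr_on_pcs <- function(scores, SR, threshold = 0.05) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  if (nrow(scores) != length(SR)) {
    stop("'scores' and 'SR' must agree in length", call. = FALSE)
  }
  if (ncol(scores) < 1L) stop("need at least one retained component",
                              call. = FALSE)
  keep <- colnames(scores)
  trace <- data.frame(dropped = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  repeat {
    dat <- data.frame(SR = SR, scores[, keep, drop = FALSE])
    fit <- stats::lm(SR ~ ., data = dat)
    cf <- summary(fit)$coefficients
    rn <- setdiff(rownames(cf), "(Intercept)")
    pv <- stats::setNames(cf[rn, "Pr(>|t|)"], rn)
    if (length(keep) == 0L || all(pv < threshold)) break
    worst <- names(pv)[which.max(pv)]
    trace <- rbind(trace, data.frame(dropped = worst,
                                     p_value = max(pv)))
    keep <- setdiff(keep, worst)
    if (length(keep) == 0L) {            # nothing qualifies: intercept only
      fit <- stats::lm(SR ~ 1, data = data.frame(SR = SR))
      cf <- summary(fit)$coefficients
      break
    }
  }
  s <- summary(fit)
  fstat <- if (is.null(s$fstatistic)) {
    c(value = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_)
  } else {
    c(value = unname(s$fstatistic["value"]),
      df1 = unname(s$fstatistic["numdf"]),
      df2 = unname(s$fstatistic["dendf"]),
      p = unname(stats::pf(s$fstatistic["value"], s$fstatistic["numdf"],
                           s$fstatistic["dendf"], lower.tail = FALSE)))
  }
  structure(
    list(fit = fit, coefficients = cf, r_squared = s$r.squared,
         f_statistic = fstat, retained = keep, threshold = threshold,
         trace = trace),
    class = "sr_regression"
  )
}

#' @export
print.sr_regression <- function(x, ...) {
  cat("Regression of species richness on principal components\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "none (intercept only)", "\n")
  if (nrow(x$trace)) {
    cat("  eliminated:",
        paste(sprintf("%s (p = %.3g)", x$trace$dropped, x$trace$p_value),
              collapse = ", "), "\n")
  }
  if (!is.na(x$f_statistic["value"])) {
    cat(sprintf("  F(%d,%d) = %.4g, R^2 = %.3f, p = %.3g\n",
                x$f_statistic["df1"], x$f_statistic["df2"],
                x$f_statistic["value"], x$r_squared, x$f_statistic["p"]))
  }
  stats::printCoefmat(x$coefficients)
  invisible(x)
}
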