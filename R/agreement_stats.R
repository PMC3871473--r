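# Agreement statistics between stroke work and the cardiac power integral:
# per-animal through-origin regression/correlation, Bland-Altman summaries,
# and a no-intercept random-slope mixed model (animal random, condition
# fixed) fit by profiled REML over the rank-one per-animal covariance.

#' Least-squares regression through the origin
#'
#' Fits `y = slope * x` with no intercept (zero stroke work necessarily
#' means zero transferred energy). Reports the through-origin slope
#' `sum(xy)/sum(x^2)` with its naive OLS 95% CI on `n - 1` df, the
#' uncentered R-squared `(sum(xy))^2 / (sum(x^2) sum(y^2))` (the "no
#' constant" correlation), and the conventional centered Pearson r for
#' reference.
#'
#' @param x,y Numeric vectors of equal length (Joules in the SW/PWR use).
#' @return List of class `origin_fit`: `slope`, `ci95_low`, `ci95_high`,
#'   `se`, `r2_uncentered`, `pearson_r`, `n`.
#' @export
through_origin_fit <- function(x, y) {
  if (length(x) != length(y)) stop("through_origin_fit: lengths differ")
  n <- length(x)
  if (n < 2) stop("through_origin_fit: need n >= 2")
  sxx <- sum(x^2)
  if (sxx == 0) stop("through_origin_fit: degenerate fit (all x zero)")
  sxy <- sum(x * y)
  syy <- sum(y^2)
  slope <- sxy / sxx
  rss <- sum((y - slope * x)^2)
  se <- sqrt(rss / (n - 1) / sxx)
  tq <- qt(0.975, n - 1)
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  structure(list(slope = slope,
                 ci95_low = slope - tq * se,
                 ci95_high = slope + tq * se,
                 se = se,
                 r2_uncentered = r2,
                 pearson_r = if (n > 2 && sd(x) > 0 && sd(y) > 0)
                   stats::cor(x, y) else NA_real_,
                 n = n),
            class = "origin_fit")
}

#' Bland-Altman agreement summary
#'
#' Differences are `sw - pwr` (power integral subtracted from stroke work);
#' limits of agreement are the mean difference plus/minus 1.96 standard
#' deviations (n - 1 denominator). The paired `(mean, diff)` points are
#' returned for plotting.
#'
#' @param sw,pwr Numeric vectors of equal length (Joules).
#' @return List of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `points` (data.frame of `mean` and `diff`).
#' @export
bland_altman <- function(sw, pwr) {
  if (length(sw) != length(pwr)) stop("bland_altman: lengths differ")
  n <- length(sw)
  if (n < 2) stop("bland_altman: need n >= 2")
  d <- sw - pwr
  m <- (sw + pwr) / 2
  md <- mean(d)
  sdd <- sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                 n = n, points = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

# Profiled (RE)ML machinery for the no-intercept random-slope model
#   y_ij = (beta_{c(ij)} + b_i) x_ij + e_ij,  b_i ~ N(0, tau2), e ~ N(0, s2)
# Per animal i, V_i = s2 (I + lambda x_i x_i'), lambda = tau2/s2; Woodbury
# gives W_i = V_i^{-1} s2 = I - lambda x_i x_i' / (1 + lambda s_i) with
# s_i = x_i'x_i, and log|V_i| = n_i log s2 + log(1 + lambda s_i).

.mixed_prep <- function(x, y, animal, condition, reference) {
  animal <- as.character(animal)
  condition <- factor(as.character(condition))
  if (!reference %in% levels(condition))
    stop("fit_mixed_slope_model: reference condition '", reference,
         "' not present")
  condition <- stats::relevel(condition, ref = reference)
  ids <- unique(animal)
  if (length(ids) < 2)
    stop("fit_mixed_slope_model: random slope variance inestimable with a single animal")
  X <- sapply(levels(condition), function(l) x * (condition == l))
  groups <- lapply(ids, function(id) which(animal == id))
  list(X = X, y = y, x = x, groups = groups, ids = ids,
       levels = levels(condition), reference = reference)
}

# profile deviance at a given lambda; returns pieces needed downstream
.mixed_profile <- function(lambda, prep, reml = TRUE) {
  X <- prep$X; y <- prep$y; x <- prep$x
  p <- ncol(X)
  N <- length(y)
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  logdet_v <- 0
  for (g in prep$groups) {
    xi <- x[g]; Xi <- X[g, , drop = FALSE]; yi <- y[g]
    si <- sum(xi^2)
    f <- lambda / (1 + lambda * si)
    # W_i %*% M = M - f * xi (xi' M)
    XtWX <- crossprod(Xi) - f * tcrossprod(crossprod(Xi, xi))
    XtWy <- crossprod(Xi, yi) - f * crossprod(Xi, xi) * sum(xi * yi)
    A <- A + XtWX
    bvec <- bvec + XtWy
    logdet_v <- logdet_v + log1p(lambda * si)
  }
  beta <- solve(A, bvec)
  Q <- 0
  for (g in prep$groups) {
    xi <- x[g]
    ri <- y[g] - X[g, , drop = FALSE] %*% beta
    si <- sum(xi^2)
    f <- lambda / (1 + lambda * si)
    Q <- Q + sum(ri^2) - f * sum(xi * ri)^2
  }
  if (reml) {
    s2 <- Q / (N - p)
    dev <- (N - p) * (log(2 * pi) + log(s2) + 1) + logdet_v +
      determinant(A, logarithm = TRUE)$modulus[1]
  } else {
    s2 <- Q / N
    dev <- N * (log(2 * pi) + log(s2) + 1) + logdet_v
  }
  list(dev = dev, beta = drop(beta), s2 = s2, A = A, lambda = lambda)
}

#' No-intercept random-slope mixed model for the SW-to-PWR relation
#'
#' Fits `y_ij = (beta_c + b_i) x_ij + e_ij` with a per-condition fixed slope
#' `beta_c`, a per-animal random slope deviation `b_i ~ N(0, tau2)` and
#' residual `e ~ N(0, sigma2)`; no intercept in either the fixed or the
#' random part. Estimation profiles the restricted (or full) likelihood over
#' `lambda = tau2/sigma2`, exploiting the rank-one per-animal covariance.
#' Wald z-tests compare each condition's slope to the reference; the random
#' slope variance is tested by a likelihood-ratio test with the boundary
#' p-value halving.
#'
#' @param beats A beat table (or data.frame) with columns for the two energy
#'   measures, animal and condition.
#' @param reference Reference condition for the fixed-effect contrasts
#'   (default `"baseline"`).
#' @param direction `"pwr_on_sw"` regresses the PWR integral on stroke work
#'   (slopes above 1 mean PWR exceeds SW); `"sw_on_pwr"` is the transpose.
#' @param method `"REML"` (default) or `"ML"`.
#' @return List of class `mixed_fit`: `beta` (named per-condition slopes),
#'   `vcov_beta`, `tau2`, `sigma2`, `lambda`, `wald_p` (per non-reference
#'   condition vs reference), `lrt_p_random`, `deviance`, `converged`,
#'   `reference`, `method`, `n`, `n_animals`.
#' @export
fit_mixed_slope_model <- function(beats, reference = "baseline",
                                  direction = c("pwr_on_sw", "sw_on_pwr"),
                                  method = c("REML", "ML")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  reml <- method == "REML"
  x <- if (direction == "pwr_on_sw") beats$sw_J else beats$pwr_integral_J
  y <- if (direction == "pwr_on_sw") beats$pwr_integral_J else beats$sw_J
  prep <- .mixed_prep(x, y, beats$animal_id, beats$condition, reference)

  at0 <- .mixed_profile(0, prep, reml)
  if (at0$s2 <= 1e-25 * mean(prep$y^2)) {
    # perfect fit up to rounding: the pooled model is the answer
    best <- at0
    best$s2 <- 0
    opt <- list(minimum = log(1e-10), objective = at0$dev)
  } else {
    obj <- function(loglam) {
      d <- .mixed_profile(exp(loglam), prep, reml)$dev
      if (!is.finite(d)) .Machine$double.xmax else d
    }
    opt <- optimize(obj, interval = c(log(1e-10), log(1e6)), tol = 1e-8)
    best <- if (at0$dev <= opt$objective) at0
            else .mixed_profile(exp(opt$minimum), prep, reml)
  }
  converged <- (is.finite(best$dev) || best$s2 == 0) &&
    (best$lambda == 0 || opt$minimum < log(1e6) - 1e-3)  # not at upper bound

  p <- length(best$beta)
  vcov_beta <- best$s2 * solve(best$A)
  lev <- prep$levels
  names(best$beta) <- lev
  dimnames(vcov_beta) <- list(lev, lev)

  ref <- prep$reference
  others <- setdiff(lev, ref)
  wald_p <- vapply(others, function(l) {
    d <- best$beta[[l]] - best$beta[[ref]]
    v <- vcov_beta[l, l] + vcov_beta[ref, ref] - 2 * vcov_beta[l, ref]
    2 * pnorm(-abs(d / sqrt(v)))
  }, numeric(1))

  lrt <- at0$dev - best$dev
  if (!is.finite(lrt) || lrt < 0) lrt <- 0  # perfect-fit / boundary limit
  lrt_p <- if (lrt == 0) 0.5 else 0.5 * pchisq(lrt, 1, lower.tail = FALSE)

  structure(list(beta = best$beta, vcov_beta = vcov_beta,
                 tau2 = best$lambda * best$s2, sigma2 = best$s2,
                 lambda = best$lambda, wald_p = wald_p,
                 lrt_p_random = lrt_p, deviance = best$dev,
                 converged = converged, reference = ref, method = method,
                 direction = direction, n = length(y),
                 n_animals = length(prep$ids)),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s, %d beats, %d animals, direction %s\n",
              x$method, x$n, x$n_animals, x$direction))
  cat(sprintf("  tau2 = %.4g, sigma2 = %.4g, LRT p(tau2=0) = %.3g\n",
              x$tau2, x$sigma2, x$lrt_p_random))
  print(round(x$beta, 4))
  invisible(x)
}

#' Per-condition slope contrasts against the reference condition
#'
#' One row per non-reference condition with the fitted slope, its Wald 95%
#' CI and the Wald p-value for a difference from the reference slope.
#' The reference condition itself appears with its slope and CI but no
#' p-value row is produced for it against itself.
#'
#' @param fit A `mixed_fit` from [fit_mixed_slope_model()].
#' @param include_reference Prepend a row for the reference condition
#'   (p-value `NA`); default `TRUE` to mirror the per-condition table shape.
#' @return A `data.table` with `condition`, `slope`, `ci95_low`,
#'   `ci95_high`, `p_vs_reference`.
#' @export
condition_contrasts <- function(fit, include_reference = TRUE) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!fit$converged)
    stop("condition_contrasts: mixed model did not converge")
  lev <- names(fit$beta)
  se <- sqrt(diag(fit$vcov_beta))
  z <- qnorm(0.975)
  dt <- data.table::data.table(
    condition = lev,
    slope = unname(fit$beta),
    ci95_low = unname(fit$beta - z * se),
    ci95_high = unname(fit$beta + z * se),
    p_vs_reference = NA_real_)
  for (l in names(fit$wald_p)) dt[condition == l,
                                  p_vs_reference := fit$wald_p[[l]]]
  if (!include_reference) dt <- dt[condition != fit$reference]
  dt[]
}
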