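# Common S3 container for causal-effect estimates: every Mendelian
# randomization estimator in the package (two-stage IV, Wald ratio, IVW,
# MR-Egger, weighted median) returns one of these, so printing, coef and
# confint behave uniformly.

new_mr_estimate <- function(method, estimate, se, p = NULL, n_variants = NA,
                            diagnostics = list(), notes = character(0)) {
  z <- estimate / se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    method = method,
    estimate = estimate,            # causal log-OR per SD exposure
    se = se,
    ci95 = estimate + c(-1, 1) * stats::qnorm(0.975) * se,
    p = p,
    or = exp(estimate),
    or_ci95 = exp(estimate + c(-1, 1) * stats::qnorm(0.975) * se),
    n_variants = n_variants,
    diagnostics = diagnostics,
    notes = notes
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s causal estimate\n", x$method))
  cat(sprintf("  log-OR per SD: %.4f (SE %.4f)\n", x$estimate, x$se))
  cat(sprintf("  OR per SD: %s, p = %.3g\n",
              format_or(x$or, x$or_ci95[1], x$or_ci95[2], digits), x$p))
  d <- x$diagnostics
  if (!is.null(d$Q)) {
    cat(sprintf("  heterogeneity Q = %.2f on %d df (p = %.3g)\n",
                d$Q, d$Q_df, d$Q_p))
  }
  if (!is.null(d$intercept)) {
    cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
                d$intercept, d$intercept_se, d$intercept_p))
  }
  if (!is.null(d$f_stat)) {
    cat(sprintf("  first-stage F = %.1f (R^2 = %.4f)\n", d$f_stat, d$r2))
  }
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$estimate, object$method)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$estimate + c(-1, 1) * q * object$se, 1, 2,
              dimnames = list(object$method,
                              sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  m
}

#' @export
summary.mr_estimate <- function(object, ...) {
  d <- object$diagnostics
  data.frame(method = object$method,
             estimate = object$estimate, se = object$se,
             or = object$or,
             or_lo = object$or_ci95[1], or_hi = object$or_ci95[2],
             p = object$p,
             n_variants = object$n_variants,
             Q = if (!is.null(d$Q)) d$Q else NA_real_,
             egger_intercept = if (!is.null(d$intercept)) d$intercept
                               else NA_real_,
             stringsAsFactors = FALSE)
}
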