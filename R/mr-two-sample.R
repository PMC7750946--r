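#' Per-variant association scan
#'
#' Regresses a trait on each variant's dosage in turn (linear for
#' continuous traits, logistic for binary), adjusting for covariates,
#' and returns one effect size and standard error per variant on the
#' per-allele scale. This supplies the variant-exposure and
#' variant-outcome halves of a summary-statistic MR analysis.
#' Monomorphic variants are dropped with a message.
#'
#' @param dosages Numeric matrix (individuals x variants), variant ids as
#'   column names.
#' @param trait Numeric (continuous) or 0/1 (binary) vector.
#' @param covariates Optional data frame.
#' @param trait_type \code{"continuous"} or \code{"binary"}.
#' @return Data frame: \code{variant_id}, \code{beta}, \code{se}, \code{p}.
#' @export
gwas_scan <- function(dosages, trait, covariates = NULL,
                      trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  mono <- apply(dosages, 2, function(g) stats::var(g, na.rm = TRUE) == 0)
  if (any(mono)) {
    message(sum(mono), " monomorphic variant(s) dropped from scan")
    dosages <- dosages[, !mono, drop = FALSE]
  }
  cov_mat <- if (!is.null(covariates)) {
    stats::model.matrix(~ ., data = covariates)  # includes intercept
  } else {
    matrix(1, nrow(dosages), 1)
  }
  ids <- colnames(dosages)
  out <- matrix(NA_real_, length(ids), 3,
                dimnames = list(ids, c("beta", "se", "p")))
  if (trait_type == "continuous") {
    for (j in seq_along(ids)) {
      X <- cbind(cov_mat, g = dosages[, j])
      fit <- stats::lm.fit(X, trait)
      rss <- sum(fit$residuals^2)
      dfres <- length(trait) - fit$rank
      XtXinv_gg <- chol2inv(chol(crossprod(X)))[ncol(X), ncol(X)]
      se <- sqrt(rss / dfres * XtXinv_gg)
      b <- fit$coefficients["g"]
      out[j, ] <- c(b, se, 2 * stats::pt(-abs(b / se), dfres))
    }
  } else {
    y <- as.integer(trait)
    for (j in seq_along(ids)) {
      X <- cbind(cov_mat, g = dosages[, j])
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial()))
      cov_un <- chol2inv(chol(crossprod(sqrt(fit$weights) * X)))
      b <- fit$coefficients["g"]
      se <- sqrt(cov_un[ncol(X), ncol(X)])
      out[j, ] <- c(b, se, 2 * stats::pnorm(-abs(b / se)))
    }
  }
  data.frame(variant_id = ids, beta = out[, "beta"], se = out[, "se"],
             p = out[, "p"], row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble two-sample summary statistics
#'
#' Joins a variant-exposure scan and a variant-outcome scan on variant id
#' (both must already refer to the same effect allele per variant).
#'
#' @param exposure_scan,outcome_scan Data frames from
#'   \code{\link{gwas_scan}} (or read from file with columns
#'   \code{variant_id}, \code{beta}, \code{se}).
#' @param same_cohort Logical flag recording whether the two halves come
#'   from one cohort (sample overlap changes weak-instrument behaviour);
#'   stored as an attribute.
#' @return Data frame with \code{variant_id}, \code{beta_x}, \code{se_x},
#'   \code{beta_y}, \code{se_y}.
#' @export
make_summary_stats <- function(exposure_scan, outcome_scan,
                               same_cohort = TRUE) {
  m <- merge(exposure_scan[, c("variant_id", "beta", "se")],
             outcome_scan[, c("variant_id", "beta", "se")],
             by = "variant_id", suffixes = c("_x", "_y"))
  names(m) <- c("variant_id", "beta_x", "se_x", "beta_y", "se_y")
  if (any(m$se_x <= 0) || any(m$se_y <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  attr(m, "same_cohort") <- same_cohort
  m
}

check_stats <- function(stats_df, min_k = 1L) {
  need <- c("beta_x", "se_y", "beta_y")
  miss <- setdiff(need, names(stats_df))
  if (length(miss)) {
    stop("summary statistics lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(stats_df) < min_k) {
    stop(sprintf("need at least %d variants, got %d", min_k,
                 nrow(stats_df)), call. = FALSE)
  }
  if (any(stats_df$se_y <= 0)) stop("se_y must be > 0", call. = FALSE)
  invisible(stats_df)
}

#' Wald ratio causal estimate for a single variant
#'
#' The causal effect implied by one instrument: the variant-outcome effect
#' divided by the variant-exposure effect, with the first-order
#' delta-method standard error \code{se_y / |beta_x|}.
#'
#' @param beta_x Variant-exposure effect (must be nonzero).
#' @param beta_y Variant-outcome effect (log-OR).
#' @param se_y Standard error of \code{beta_y}.
#' @return An \code{"mr_estimate"}.
#' @examples
#' wald_ratio(0.1, 0.02, 0.01)
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (!is.finite(beta_x) || beta_x == 0) {
    stop("Wald ratio undefined: variant-exposure effect is zero",
         call. = FALSE)
  }
  new_mr_estimate("Wald ratio", beta_y / beta_x, se_y / abs(beta_x),
                  n_variants = 1L)
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Combines per-variant Wald ratios with weights
#' \eqn{w_i = \beta_{x,i}^2 / se_{y,i}^2}; equivalently, weighted least
#' squares of outcome effects on exposure effects through the origin with
#' weights \eqn{1/se_{y,i}^2}. Cochran's Q on the ratio scale
#' (\eqn{Q = \sum_i w_i (\theta_i - \hat\theta)^2}, df = k - 1) measures
#' heterogeneity; under the random-effects model the fixed-effects
#' standard error is inflated by \eqn{\sqrt{\max(1, Q/(k-1))}}. A single
#' variant degrades to the Wald ratio with a note.
#'
#' @param stats_df Data frame with \code{beta_x}, \code{beta_y},
#'   \code{se_y} (see \code{\link{make_summary_stats}}).
#' @param effects_model \code{"fixed"} or \code{"random"}.
#' @return An \code{"mr_estimate"} with \code{Q}, \code{Q_df}, \code{Q_p}
#'   diagnostics.
#' @export
mr_ivw <- function(stats_df, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  check_stats(stats_df, 1L)
  if (all(stats_df$beta_x == 0)) {
    stop("all variant-exposure effects are zero", call. = FALSE)
  }
  k <- nrow(stats_df)
  if (k == 1L) {
    est <- wald_ratio(stats_df$beta_x, stats_df$beta_y, stats_df$se_y)
    est$method <- "IVW"
    est$notes <- "single variant: estimate equals the Wald ratio"
    return(est)
  }
  w <- stats_df$beta_x^2 / stats_df$se_y^2
  theta <- stats_df$beta_y / stats_df$beta_x
  est <- sum(w * theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (theta - est)^2)
  Q_df <- k - 1L
  Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  infl <- if (effects_model == "random") sqrt(max(1, Q / Q_df)) else 1
  new_mr_estimate(sprintf("IVW (%s effects)", effects_model),
                  est, se_fixed * infl, n_variants = k,
                  diagnostics = list(Q = Q, Q_df = Q_df, Q_p = Q_p))
}

#' MR-Egger regression
#'
#' Weighted regression of variant-outcome on variant-exposure effects with
#' an unconstrained intercept (weights \eqn{1/se_y^2}); the slope is the
#' causal estimate and a nonzero intercept indicates directional
#' horizontal pleiotropy. Variants are oriented so every
#' variant-exposure effect is positive before fitting. Inference uses the
#' weighted-least-squares t-tests with the residual dispersion estimated
#' from the fit.
#'
#' @param stats_df Data frame with \code{beta_x}, \code{beta_y},
#'   \code{se_y}; at least 3 variants.
#' @return An \code{"mr_estimate"} with \code{intercept},
#'   \code{intercept_se}, \code{intercept_p} diagnostics.
#' @export
mr_egger <- function(stats_df) {
  check_stats(stats_df, 3L)
  flip <- sign(stats_df$beta_x)
  flip[flip == 0] <- 1
  bx <- stats_df$beta_x * flip
  by <- stats_df$beta_y * flip
  w <- 1 / stats_df$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  co <- summary(fit)$coefficients
  new_mr_estimate("MR-Egger",
                  co["bx", "Estimate"], co["bx", "Std. Error"],
                  p = co["bx", "Pr(>|t|)"],
                  n_variants = nrow(stats_df),
                  diagnostics = list(
                    intercept = co["(Intercept)", "Estimate"],
                    intercept_se = co["(Intercept)", "Std. Error"],
                    intercept_p = co["(Intercept)", "Pr(>|t|)"]))
}

# interpolated weighted median of ratio estimates theta with weights w
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(theta[1])
  if (cs[length(cs)] <= 0.5) return(theta[length(theta)])
  below <- max(which(cs < 0.5))
  theta[below] + (theta[below + 1] - theta[below]) *
    (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted-median causal estimate
#'
#' The causal effect at the 50\% point of the inverse-variance-weight-
#' ordered Wald ratios (linear interpolation between adjacent ratios).
#' Consistent when at least half of the weight comes from valid
#' instruments. The standard error comes from a seeded parametric
#' bootstrap: \code{bootstrap_B} resamples of \code{(beta_x, beta_y)} from
#' normal distributions with the reported standard errors.
#'
#' @param stats_df Data frame with \code{beta_x}, \code{se_x},
#'   \code{beta_y}, \code{se_y}; at least 3 variants.
#' @param bootstrap_B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An \code{"mr_estimate"}.
#' @export
mr_weighted_median <- function(stats_df, bootstrap_B = 1000L, seed = 1L) {
  check_stats(stats_df, 3L)
  if (!"se_x" %in% names(stats_df)) {
    stop("weighted median bootstrap needs se_x", call. = FALSE)
  }
  theta <- stats_df$beta_y / stats_df$beta_x
  w <- stats_df$beta_x^2 / stats_df$se_y^2
  est <- weighted_median_point(theta, w)
  k <- nrow(stats_df)
  set.seed(child_seed(seed, .seed_offsets[["bootstrap"]]))
  boot <- vapply(seq_len(bootstrap_B), function(b) {
    bx <- stats::rnorm(k, stats_df$beta_x, stats_df$se_x)
    by <- stats::rnorm(k, stats_df$beta_y, stats_df$se_y)
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / stats_df$se_y[ok]^2)
  }, numeric(1))
  new_mr_estimate("Weighted median", est, stats::sd(boot), n_variants = k)
}

#' Run all two-sample MR estimators
#'
#' Convenience wrapper applying IVW (random effects), MR-Egger and the
#' weighted median to one summary-statistics table.
#'
#' @param stats_df Summary statistics (see
#'   \code{\link{make_summary_stats}}).
#' @param bootstrap_B,seed Passed to \code{\link{mr_weighted_median}}.
#' @return Named list of \code{"mr_estimate"} objects.
#' @export
mr_two_sample <- function(stats_df, bootstrap_B = 1000L, seed = 1L) {
  list(ivw = mr_ivw(stats_df),
       egger = mr_egger(stats_df),
       weighted_median = mr_weighted_median(stats_df, bootstrap_B, seed))
}

#' Read a two-sample summary-statistics file
#'
#' Tab-separated with header \code{variant_id}, \code{effect_allele},
#' \code{beta_x}, \code{se_x}, \code{p_x}, \code{beta_y}, \code{se_y},
#' \code{p_y} (allele and p columns optional).
#'
#' @param path File path.
#' @return Data frame suitable for the \code{mr_*} estimators.
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_stats(x)
  x
}
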