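#' Rank-based inverse-normal transform
#'
#' Maps values to normal scores using the Blom offset:
#' \eqn{\Phi^{-1}((r - 3/8) / (m + 1/4))} where r is the (average-tie)
#' rank among the m non-missing values. Missing entries are preserved.
#' Continuous exposures are put through this transform before modelling so
#' effect estimates read per standard deviation.
#'
#' @param values Numeric vector.
#' @return Numeric vector of z-scores, same length, NAs in place.
#' @examples
#' inverse_normal(c(-2, 0, 5))
#' @export
inverse_normal <- function(values) {
  ok <- !is.na(values)
  m <- sum(ok)
  if (m < 2) stop("need at least 2 non-missing values", call. = FALSE)
  if (length(unique(values[ok])) == 1L) {
    stop("all values identical: inverse-normal transform undefined",
         call. = FALSE)
  }
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (m + 1 / 4))
  out
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' predictor, optionally adjusting for covariates (age and sex in the
#' canonical use). Reports the log-odds ratio per unit of the predictor
#' (per SD if the predictor was inverse-normalized), its Wald 95\% CI on
#' the odds-ratio scale, and complete-case counts. On an unadjusted 2x2
#' table the estimate equals the cross-product odds ratio exactly.
#' Fits showing separation (non-convergence or fitted probabilities at the
#' boundary) are flagged and the estimate withheld.
#'
#' @param outcome Binary 0/1 (or logical) vector with both classes present.
#' @param predictor Numeric or binary vector.
#' @param covariates Optional data frame of covariates.
#' @return Object of class \code{"assoc_result"}: list with
#'   \code{estimate} (log-OR), \code{se}, \code{or}, \code{ci95} (OR
#'   scale), \code{p}, \code{n_used}, \code{n_missing}, \code{converged},
#'   \code{separation}, \code{model}.
#' @examples
#' ## crude odds ratio from a 2x2 table: 19971/8093 cases,
#' ## 221046/71128 controls by exposure
#' tab <- assoc_from_counts(19971, 8093, 221046, 71128)
#' tab$or  # cross-product ratio
#' @export
logistic_assoc <- function(outcome, predictor, covariates = NULL) {
  y <- as.integer(outcome)
  df <- data.frame(.y = y, .x = predictor)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (length(unique(df$.y)) < 2L) {
    stop("outcome must have both classes present", call. = FALSE)
  }
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  co <- summary(fit)$coefficients
  est <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  if (sep) est <- se <- NA_real_
  p <- if (sep) NA_real_ else co[".x", "Pr(>|z|)"]
  structure(list(
    estimate = est, se = se,
    or = exp(est),
    ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
    p = p,
    n_used = nrow(df), n_missing = sum(!cc),
    converged = fit$converged, separation = sep,
    model = paste(".y ~ .x",
                  if (!is.null(covariates))
                    paste("+", paste(names(covariates), collapse = " + "))
                  else "")
  ), class = "assoc_result")
}

#' Crude odds ratio from 2x2 counts
#'
#' Convenience wrapper: expands case/control counts by exposure into
#' individual rows and fits the unadjusted logistic model, whose odds
#' ratio coincides with the cross-product ratio \eqn{ad/bc}.
#'
#' @param case_exposed,case_unexposed,control_exposed,control_unexposed
#'   Cell counts.
#' @return An \code{"assoc_result"}.
#' @export
assoc_from_counts <- function(case_exposed, case_unexposed,
                              control_exposed, control_unexposed) {
  y <- rep(c(1L, 1L, 0L, 0L),
           c(case_exposed, case_unexposed,
             control_exposed, control_unexposed))
  x <- rep(c(1L, 0L, 1L, 0L),
           c(case_exposed, case_unexposed,
             control_exposed, control_unexposed))
  logistic_assoc(y, x)
}

#' Linear covariate-adjusted association
#'
#' Least-squares analogue of \code{\link{logistic_assoc}} for continuous
#' outcomes (used e.g. for score-versus-trait pleiotropy screens).
#'
#' @inheritParams logistic_assoc
#' @return An \code{"assoc_result"} with \code{estimate} a slope and
#'   \code{or}/\code{ci95} reported on the identity scale.
#' @export
linear_assoc <- function(outcome, predictor, covariates = NULL) {
  df <- data.frame(.y = outcome, .x = predictor)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  fit <- stats::lm(.y ~ ., data = df)
  co <- summary(fit)$coefficients
  est <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  structure(list(
    estimate = est, se = se,
    or = est,  # identity scale
    ci95 = est + c(-1, 1) * stats::qnorm(0.975) * se,
    p = co[".x", "Pr(>|t|)"],
    n_used = nrow(df), n_missing = sum(!cc),
    converged = TRUE, separation = FALSE,
    model = "linear"
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (x$separation) {
    cat("Association: separation detected; estimate withheld\n")
  } else if (x$model == "linear") {
    cat(sprintf("Slope %.4f (95%% CI %.4f to %.4f), p = %.3g, n = %d\n",
                x$estimate, x$ci95[1], x$ci95[2], x$p, x$n_used))
  } else {
    cat(sprintf("OR %s, p = %.3g, n = %d (missing %d)\n",
                format_or(x$or, x$ci95[1], x$ci95[2]), x$p,
                x$n_used, x$n_missing))
  }
  invisible(x)
}

#' Case/control demographics table with adjusted odds ratios
#'
#' Summarizes each requested trait by case status (mean +/- SD for
#' continuous traits; N and percent for binary ones) and attaches the
#' age/sex-adjusted odds ratio of case status per unit of the trait
#' (per SD after inverse-normalization for continuous traits), analysis
#' performed complete-case per trait.
#'
#' @param cohort Data frame with the trait columns plus \code{age} and
#'   \code{sex}.
#' @param status Binary case indicator (0/1) aligned with \code{cohort}
#'   rows.
#' @param traits Character vector of trait column names.
#' @param adjust Character vector of covariate columns (default age, sex).
#' @return Data frame with one row per trait: summaries by group, OR, CI
#'   bounds and p.
#' @export
summarize_cohort <- function(cohort, status, traits,
                             adjust = c("age", "sex")) {
  status <- as.integer(status)
  rows <- lapply(traits, function(tr) {
    v <- cohort[[tr]]
    binary <- is.logical(v) || all(stats::na.omit(v) %in% 0:1)
    if (binary) {
      v <- as.integer(v)
      sum_ctrl <- sprintf("%d (%.1f%%)", sum(v[status == 0], na.rm = TRUE),
                          100 * mean(v[status == 0], na.rm = TRUE))
      sum_case <- sprintf("%d (%.1f%%)", sum(v[status == 1], na.rm = TRUE),
                          100 * mean(v[status == 1], na.rm = TRUE))
      pred <- v
    } else {
      sum_ctrl <- sprintf("%.2f ± %.2f", mean(v[status == 0], na.rm = TRUE),
                          stats::sd(v[status == 0], na.rm = TRUE))
      sum_case <- sprintf("%.2f ± %.2f", mean(v[status == 1], na.rm = TRUE),
                          stats::sd(v[status == 1], na.rm = TRUE))
      pred <- inverse_normal(v)
    }
    covs <- if (length(adjust) && !tr %in% adjust)
      cohort[, setdiff(adjust, tr), drop = FALSE] else NULL
    a <- if (length(unique(stats::na.omit(status))) < 2L) {
      # degenerate cohort (no cases or no controls): summaries only
      list(or = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
           n_used = sum(!is.na(pred) & !is.na(status)))
    } else {
      logistic_assoc(status, pred, covs)
    }
    data.frame(trait = tr, controls = sum_ctrl, cases = sum_case,
               or = a$or, ci_low = a$ci95[1], ci_high = a$ci95[2],
               p = a$p, n_used = a$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
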