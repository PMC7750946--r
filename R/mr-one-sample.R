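#' One-sample Mendelian randomization by two-stage estimation
#'
#' Stage 1 regresses the (inverse-normalized) exposure on the genetic risk
#' score and covariates by least squares; stage 2 fits a logistic model of
#' the binary outcome on the stage-1 fitted values and the same
#' covariates. The coefficient on the fitted values is the causal log-odds
#' ratio per SD of exposure, free of confounding under the instrumental-
#' variable assumptions. The default standard error is the stage-2 model
#' SE, which ignores first-stage uncertainty (flagged as uncorrected); an
#' optional nonparametric bootstrap refits both stages on resampled
#' individuals. The estimate is invariant to affine rescaling of the
#' score, and with no covariates equals the ratio of the score-outcome
#' logistic coefficient to the score-exposure linear coefficient.
#'
#' @param score Genetic risk score vector (e.g. WGRS).
#' @param exposure Continuous exposure vector.
#' @param outcome Binary 0/1 outcome vector.
#' @param covariates Optional data frame (canonically age, sex, principal
#'   components, centre, platform).
#' @param invnorm Inverse-normalize the exposure first so the estimate is
#'   per SD (default TRUE).
#' @param f_floor Warn if the first-stage partial F falls below this
#'   (default 10, the conventional weak-instrument floor).
#' @param bootstrap_B If > 0, number of bootstrap resamples for the SE.
#' @param seed Seed for the bootstrap.
#' @return An \code{"mr_estimate"} (method \code{"Two-stage IV"}) with
#'   first-stage \code{f_stat} and \code{r2} diagnostics and the two fitted
#'   stage models in \code{diagnostics$stages}.
#' @export
mr_two_stage <- function(score, exposure, outcome, covariates = NULL,
                         invnorm = TRUE, f_floor = 10,
                         bootstrap_B = 0L, seed = 1L) {
  y <- outcome
  if (!all(stats::na.omit(y) %in% 0:1)) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  if (length(unique(stats::na.omit(y))) < 2L) {
    stop("outcome must have both classes present", call. = FALSE)
  }
  df <- data.frame(.g = score, .x = exposure, .y = as.integer(y))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (invnorm) df$.x <- inverse_normal(df$.x)

  s1 <- stats::lm(.x ~ . - .y, data = df)
  b1 <- stats::coef(s1)[".g"]
  if (!is.finite(b1) || abs(b1) < 1e-12 * stats::sd(df$.x)) {
    stop("stage-1 slope is (numerically) zero: causal estimate undefined",
         call. = FALSE)
  }
  strength <- grs_strength(df$.g, df$.x,
                           if (!is.null(covariates))
                             df[, setdiff(names(df), c(".g", ".x", ".y")),
                                drop = FALSE] else NULL)
  notes <- "stage-2 model SE; first-stage uncertainty not propagated"
  if (strength$f_stat < f_floor) {
    warning(sprintf("first-stage F = %.2f below floor %.1f: weak instrument",
                    strength$f_stat, f_floor), call. = FALSE)
  }
  df$.xhat <- stats::fitted(s1)
  s2 <- stats::glm(.y ~ . - .x - .g, data = df, family = stats::binomial())
  co <- summary(s2)$coefficients
  est <- co[".xhat", "Estimate"]
  se <- co[".xhat", "Std. Error"]

  if (bootstrap_B > 0L) {
    set.seed(child_seed(seed, .seed_offsets[["bootstrap"]]))
    n <- nrow(df)
    bs <- vapply(seq_len(bootstrap_B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      d <- df[i, setdiff(names(df), ".xhat"), drop = FALSE]
      f1 <- stats::lm(.x ~ . - .y, data = d)
      d$.xhat <- stats::fitted(f1)
      f2 <- suppressWarnings(
        stats::glm(.y ~ . - .x - .g, data = d, family = stats::binomial()))
      stats::coef(f2)[".xhat"]
    }, numeric(1))
    se <- stats::sd(bs)
    notes <- sprintf("nonparametric bootstrap SE (B = %d)", bootstrap_B)
  }
  new_mr_estimate("Two-stage IV", est, se,
                  n_variants = NA_integer_,
                  diagnostics = list(f_stat = strength$f_stat,
                                     r2 = strength$r2,
                                     stage1 = s1, stage2 = s2),
                  notes = notes)
}

#' Rescale an odds ratio from per-SD to per-unit of a measured trait
#'
#' Converts an odds ratio expressed per standard deviation of an exposure
#' into an odds ratio per a chosen number of measurement units, given how
#' many units one SD corresponds to:
#' \eqn{OR_{target} = \exp(\ln(OR_{SD}) \cdot target / units\_per\_sd)}.
#' Used e.g. to express a per-SD waist-hip-ratio effect per 5 cm of waist
#' circumference. Composes: rescaling to u then to v equals rescaling to v
#' directly.
#'
#' @param or_per_sd Odds ratio per SD (> 0).
#' @param units_per_sd Measurement units corresponding to one SD (> 0).
#' @param target_units Units to express the effect per (> 0).
#' @return Odds ratio per \code{target_units}.
#' @examples
#' rescale_per_unit(1.19, units_per_sd = 4.2, target_units = 5)  # ~1.23
#' @export
rescale_per_unit <- function(or_per_sd, units_per_sd, target_units) {
  if (or_per_sd <= 0 || units_per_sd <= 0 || target_units <= 0) {
    stop("all arguments must be positive", call. = FALSE)
  }
  exp(log(or_per_sd) * target_units / units_per_sd)
}

#' Analytic power for one-sample MR with a binary outcome
#'
#' Normal approximation based on the non-centrality of the score-outcome
#' test: with a score explaining \code{r2} of the exposure variance and a
#' causal odds ratio \code{or_alternative} per SD of exposure,
#' \deqn{power = \Phi(\sqrt{n r^2 \phi (1-\phi)} |\ln OR| - z_{1-\alpha/2})
#'   + \Phi(-\sqrt{n r^2 \phi (1-\phi)} |\ln OR| - z_{1-\alpha/2})}
#' where \eqn{\phi} is the case fraction. Power is non-decreasing in n,
#' r2 and |ln OR|. With \code{r2 = 0} the test has power alpha by
#' construction.
#'
#' @param n Sample size.
#' @param r2_instrument Variance of the exposure explained by the score.
#' @param or_alternative Causal odds ratio per SD under the alternative.
#' @param case_fraction Fraction of cases in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in [alpha, 1]; attribute \code{note} when r2 = 0.
#' @examples
#' mr_power(n = 379713, r2_instrument = 0.015, or_alternative = 1.28,
#'          case_fraction = 0.09)
#' @export
mr_power <- function(n, r2_instrument, or_alternative, case_fraction,
                     alpha = 0.05) {
  if (n <= 0 || r2_instrument < 0 || r2_instrument > 1 ||
      or_alternative <= 0 || case_fraction <= 0 || case_fraction >= 1 ||
      alpha <= 0 || alpha >= 1) {
    stop("arguments out of range", call. = FALSE)
  }
  if (r2_instrument == 0) {
    out <- alpha
    attr(out, "note") <- "r2 = 0: power equals the significance level"
    return(out)
  }
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- sqrt(n * r2_instrument * case_fraction * (1 - case_fraction)) *
    abs(log(or_alternative))
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}
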