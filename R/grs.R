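#' Read an instrument-weight table
#'
#' Tab-separated with header \code{variant_id}, \code{effect_allele},
#' \code{other_allele}, \code{beta}, \code{se}, \code{p}, \code{trait}.
#' Duplicate variant ids, non-finite betas and non-positive standard
#' errors are rejected.
#'
#' @param path File path.
#' @return Data frame of instrument weights.
#' @export
read_instruments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_instruments(x)
}

validate_instruments <- function(x) {
  need <- c("variant_id", "effect_allele", "other_allele", "beta")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("instrument table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$variant_id)) {
    stop("duplicate variant_id in instrument table", call. = FALSE)
  }
  if (any(!is.finite(x$beta))) stop("non-finite beta in instrument table",
                                    call. = FALSE)
  if ("se" %in% names(x) && any(!is.na(x$se) & x$se <= 0)) {
    stop("instrument se must be > 0", call. = FALSE)
  }
  x
}

is_strand_ambiguous <- function(ea, oa) {
  p <- paste0(toupper(ea), toupper(oa))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize instrument weights with a dosage panel
#'
#' Aligns each instrument's effect allele with the allele counted in the
#' dosage file. Where the allele pair is the same but swapped, the dosage
#' is recoded g -> 2 - g (orientation flip), which preserves the sign of
#' the per-allele weight. Variants with incompatible allele pairs are
#' dropped with a warning. Palindromic (A/T, C/G) variants cannot be
#' strand-checked and are flagged; with \code{strict = TRUE} they are
#' dropped.
#'
#' @param instruments Instrument table (see \code{\link{read_instruments}}).
#' @param variants Variant panel with \code{variant_id},
#'   \code{effect_allele}, \code{other_allele} and optionally \code{eaf}.
#' @param strict Drop strand-ambiguous variants instead of keeping them
#'   with a flag.
#' @return Object of class \code{"harmonized_instruments"}: list with
#'   \code{instruments} (aligned rows, plus logical columns \code{flip},
#'   \code{ambiguous}), \code{n_dropped} and \code{dropped_ids}. Applying
#'   the function to its own output is the identity.
#' @export
harmonize_instruments <- function(instruments, variants, strict = FALSE) {
  instruments <- validate_instruments(instruments)
  idx <- match(instruments$variant_id, variants$variant_id)
  present <- !is.na(idx)
  dropped <- instruments$variant_id[!present]
  ins <- instruments[present, , drop = FALSE]
  vr <- variants[idx[present], , drop = FALSE]

  same <- toupper(ins$effect_allele) == toupper(vr$effect_allele) &
    toupper(ins$other_allele) == toupper(vr$other_allele)
  swapped <- toupper(ins$effect_allele) == toupper(vr$other_allele) &
    toupper(ins$other_allele) == toupper(vr$effect_allele)
  mismatch <- !(same | swapped)
  if (any(mismatch)) {
    dropped <- c(dropped, ins$variant_id[mismatch])
    ins <- ins[!mismatch, , drop = FALSE]
    vr <- vr[!mismatch, , drop = FALSE]
    same <- same[!mismatch]; swapped <- swapped[!mismatch]
  }
  amb <- is_strand_ambiguous(ins$effect_allele, ins$other_allele)
  if (strict && any(amb)) {
    dropped <- c(dropped, ins$variant_id[amb])
    ins <- ins[!amb, , drop = FALSE]; vr <- vr[!amb, , drop = FALSE]
    same <- same[!amb]; swapped <- swapped[!amb]
    amb <- amb[!amb]
  }
  if (length(dropped)) {
    warning(sprintf("%d instrument(s) dropped during harmonization: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  ins$flip <- swapped
  ins$ambiguous <- amb
  if ("eaf" %in% names(vr)) {
    # panel EAF for the instrument's effect allele (after orientation)
    ins$panel_eaf <- ifelse(swapped, 1 - vr$eaf, vr$eaf)
  }
  structure(list(instruments = ins,
                 n_dropped = length(dropped),
                 dropped_ids = dropped),
            class = "harmonized_instruments")
}

#' @export
print.harmonized_instruments <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %d kept (%d flipped, %d strand-ambiguous), %d dropped\n",
              nrow(x$instruments), sum(x$instruments$flip),
              sum(x$instruments$ambiguous), x$n_dropped))
  invisible(x)
}

# Orient a dosage matrix to a harmonized instrument table: flip g -> 2 - g
# where the weight file's effect allele is the panel's other allele.
oriented_dosages <- function(dosages, harmonized) {
  ins <- if (inherits(harmonized, "harmonized_instruments"))
    harmonized$instruments else harmonized
  miss <- setdiff(ins$variant_id, colnames(dosages))
  if (length(miss)) {
    stop("dosage matrix lacks variants: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  d <- dosages[, ins$variant_id, drop = FALSE]
  if (!is.null(ins$flip) && any(ins$flip)) {
    d[, ins$flip] <- 2 - d[, ins$flip, drop = FALSE]
  }
  d
}

#' Weighted genetic risk score
#'
#' Computes the raw weighted score for each individual: the sum over
#' variants of the per-allele exposure weight times the (harmonized)
#' effect-allele dosage, \eqn{W_s = \sum_i \beta_i \, g_i}. Missing
#' dosages are mean-imputed to twice the effect-allele frequency before
#' summation; the number of imputed entries is reported as an attribute.
#'
#' @param dosages Numeric matrix (individuals x variants) with variant ids
#'   as column names; already oriented, or pass the
#'   \code{"harmonized_instruments"} object so orientation is applied.
#' @param instruments Instrument table or \code{"harmonized_instruments"}.
#' @return Numeric vector of raw scores, attribute \code{n_imputed}.
#' @examples
#' d <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("v1", "v2")))
#' w <- data.frame(variant_id = c("v1", "v2"),
#'                 effect_allele = "A", other_allele = "G",
#'                 beta = c(0.1, 0.3))
#' grs_score(d, w)  # 0.1*1 + 0.3*2 = 0.7
#' @export
grs_score <- function(dosages, instruments) {
  ins <- if (inherits(instruments, "harmonized_instruments")) {
    dosages <- oriented_dosages(dosages, instruments)
    instruments$instruments
  } else {
    validate_instruments(instruments)
  }
  d <- dosages[, ins$variant_id, drop = FALSE]
  na_count <- colSums(is.na(d))
  if (any(na_count == nrow(d))) {
    stop("variant(s) with all dosages missing: ",
         paste(ins$variant_id[na_count == nrow(d)], collapse = ", "),
         call. = FALSE)
  }
  n_imp <- sum(na_count)
  if (n_imp > 0) {
    eaf <- if (!is.null(ins$panel_eaf)) ins$panel_eaf else
      colMeans(d, na.rm = TRUE) / 2
    for (j in which(na_count > 0)) {
      d[is.na(d[, j]), j] <- 2 * eaf[j]
    }
  }
  ws <- drop(d %*% ins$beta)
  attr(ws, "n_imputed") <- n_imp
  ws
}

#' Rescale a weighted score to the trait-raising allele count scale
#'
#' \eqn{WGRS = W_s \cdot n / \sum_i \beta_i}, where n is the number of
#' variants: the score then reads as an (effective) number of trait-raising
#' alleles, invariant to multiplying all weights by a positive constant.
#' With all weights equal it reduces to the raw allele count.
#'
#' @param ws Raw weighted score vector from \code{\link{grs_score}}.
#' @param instruments Instrument table or \code{"harmonized_instruments"}
#'   (the same one used for \code{ws}).
#' @return Numeric vector of rescaled scores.
#' @export
grs_rescale <- function(ws, instruments) {
  ins <- if (inherits(instruments, "harmonized_instruments"))
    instruments$instruments else validate_instruments(instruments)
  sb <- sum(ins$beta)
  if (abs(sb) < .Machine$double.eps) {
    stop("sum of instrument weights is zero: rescaled score undefined",
         call. = FALSE)
  }
  as.numeric(ws) * nrow(ins) / sb
}

#' Instrument strength of a genetic risk score
#'
#' Fits \code{exposure ~ score + covariates} by least squares and reports
#' the incremental variance explained by the score beyond the covariates,
#' the corresponding partial F statistic (with no covariates this is
#' \eqn{F = R^2 (n - k - 1) / (1 - R^2)} for the single added regressor),
#' the per-unit slope and its p-value. Large F indicates no weak-instrument
#' bias.
#'
#' @param score Numeric score vector (e.g. WGRS).
#' @param exposure Numeric exposure vector.
#' @param covariates Optional data frame of covariates.
#' @return List with \code{r2} (incremental), \code{f_stat}, \code{slope},
#'   \code{se}, \code{p}, \code{n}.
#' @export
grs_strength <- function(score, exposure, covariates = NULL) {
  if (stats::sd(score, na.rm = TRUE) == 0) {
    stop("score is constant: instrument strength undefined", call. = FALSE)
  }
  df <- data.frame(.y = exposure, .g = score)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  k <- ncol(df) - 1L  # regressors in the full model (score + covariates)
  if (n <= k + 2) stop("too few complete observations", call. = FALSE)
  full <- stats::lm(.y ~ ., data = df)
  r2_full <- summary(full)$r.squared
  if (is.null(covariates)) {
    r2_inc <- r2_full
  } else {
    red <- stats::lm(.y ~ . - .g, data = df)
    r2_inc <- r2_full - summary(red)$r.squared
  }
  p_full <- length(stats::coef(full))
  f <- if (r2_full >= 1) Inf else r2_inc * (n - p_full) / (1 - r2_full)
  sm <- summary(full)$coefficients[".g", ]
  list(r2 = r2_inc, f_stat = f,
       slope = unname(sm[1]), se = unname(sm[2]), p = unname(sm[4]),
       n = n)
}
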