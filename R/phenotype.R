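# Code dictionaries for the reflux phenotype. Self-report 1138 is the
# questionnaire code for GORD/gastric reflux; K21.9/K21.0 are the ICD10
# reflux codes without/with esophagitis; G24/G25 are OPCS4 anti-reflux
# operations (primary and revision); G45 is diagnostic upper-GI endoscopy.
.gord_codes <- list(
  self_report = "1138",
  icd10 = c("K21.9", "K21.0"),
  icd10_esophagitis = "K21.0",
  opcs4_surgery = c("G24", "G25"),
  opcs4_endoscopy = "G45"
)

# split comma-separated code strings into a list of character sets
split_codes <- function(x) {
  x[is.na(x)] <- ""
  strsplit(as.character(x), ",", fixed = TRUE)
}

has_any <- function(code_list, codes) {
  vapply(code_list, function(s) any(s %in% codes), logical(1))
}

#' Derive nested reflux case/control definitions from code lists
#'
#' Implements a four-level phenotype algorithm over self-report, ICD10
#' diagnosis and OPCS4 procedure codes, each level trading cases for
#' diagnostic certainty:
#' \describe{
#'   \item{primary}{case if self-report 1138, or ICD10 K21.9/K21.0, or an
#'     anti-reflux operation code G24/G25 is present; everyone else is a
#'     control.}
#'   \item{sa1}{cases whose only evidence is the self-report code are
#'     excluded; controls on acid-suppressant medication or with an
#'     endoscopy code G45 are excluded (possible undiagnosed reflux).}
#'   \item{sa2}{additionally excludes cases without the esophagitis code
#'     K21.0; controls as sa1.}
#'   \item{sa3}{keeps only cases that underwent anti-reflux surgery
#'     (G24/G25) and carry at least one other confirming code
#'     (1138, K21.9 or K21.0); controls as sa1.}
#' }
#' The case sets are nested: sa3 within sa2 within sa1 within primary, and
#' control exclusions never create cases.
#'
#' @param cohort Data frame with columns \code{id},
#'   \code{self_report_codes}, \code{icd10_codes}, \code{opcs4_codes}
#'   (comma-separated code strings; empty for none),
#'   \code{on_acid_suppressant}, \code{had_endoscopy_g45} (logical).
#' @return Object of class \code{"gord_status"}: data frame with \code{id},
#'   \code{primary} (\code{"case"}/\code{"control"}) and \code{sa1},
#'   \code{sa2}, \code{sa3} (\code{"case"}/\code{"control"}/
#'   \code{"excluded"}).
#' @examples
#' d <- data.frame(id = c("a", "b", "c"),
#'                 self_report_codes = c("1138", "", ""),
#'                 icd10_codes = c("", "K21.0", ""),
#'                 opcs4_codes = c("", "G24", ""),
#'                 on_acid_suppressant = c(FALSE, FALSE, TRUE),
#'                 had_endoscopy_g45 = FALSE)
#' derive_gord(d)
#' @export
derive_gord <- function(cohort) {
  need <- c("id", "self_report_codes", "icd10_codes", "opcs4_codes",
            "on_acid_suppressant", "had_endoscopy_g45")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sr <- split_codes(cohort$self_report_codes)
  icd <- split_codes(cohort$icd10_codes)
  ops <- split_codes(cohort$opcs4_codes)

  ev_self <- has_any(sr, .gord_codes$self_report)
  ev_icd <- has_any(icd, .gord_codes$icd10)
  ev_k210 <- has_any(icd, .gord_codes$icd10_esophagitis)
  ev_surg <- has_any(ops, .gord_codes$opcs4_surgery)

  case <- ev_self | ev_icd | ev_surg
  primary <- ifelse(case, "case", "control")

  # control exclusions shared by every sensitivity level
  ctrl_excl <- !case & (cohort$on_acid_suppressant | cohort$had_endoscopy_g45)

  sa1 <- primary
  sa1[case & ev_self & !ev_icd & !ev_surg] <- "excluded"
  sa1[ctrl_excl] <- "excluded"

  sa2 <- sa1
  sa2[sa1 == "case" & !ev_k210] <- "excluded"

  sa3 <- sa2
  other_confirm <- ev_self | ev_icd
  sa3[sa2 == "case" & !(ev_surg & other_confirm)] <- "excluded"

  structure(data.frame(id = cohort$id, primary = primary,
                       sa1 = sa1, sa2 = sa2, sa3 = sa3,
                       stringsAsFactors = FALSE),
            class = c("gord_status", "data.frame"))
}

#' @export
print.gord_status <- function(x, ...) {
  cat("Reflux phenotype status (", nrow(x), " individuals)\n", sep = "")
  print(tabulate_flowchart(x))
  invisible(x)
}

#' Tabulate the phenotype-definition flowchart
#'
#' Counts cases, controls and exclusions at each definition level and
#' checks that the case counts are monotonically nested
#' (sa3 <= sa2 <= sa1 <= primary).
#'
#' @param status A \code{"gord_status"} table from \code{\link{derive_gord}}.
#' @return Data frame with one row per level and columns \code{level},
#'   \code{cases}, \code{controls}, \code{excluded}.
#' @export
tabulate_flowchart <- function(status) {
  lv <- c("primary", "sa1", "sa2", "sa3")
  out <- do.call(rbind, lapply(lv, function(l) {
    s <- status[[l]]
    data.frame(level = l,
               cases = sum(s == "case"),
               controls = sum(s == "control"),
               excluded = sum(s == "excluded"),
               stringsAsFactors = FALSE)
  }))
  if (any(diff(out$cases) > 0)) {
    stop("internal error: case counts are not nested across levels",
         call. = FALSE)
  }
  out
}
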