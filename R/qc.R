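#' Greedy selection of an unrelated subset
#'
#' Given kinship pairs (third-degree relatives or closer), repeatedly
#' removes an individual with the current maximum number of remaining
#' relatives until no related pair is left, which keeps the retained set as
#' large as the greedy rule allows. If A is related to B and C but B and C
#' are unrelated, A is removed. When the maximum relative count is one
#' (simple pairs only), one member of a pair is dropped at random; residual
#' ties between equal-count individuals are broken by lowest id so the
#' procedure is reproducible under a fixed seed.
#'
#' @param individual_ids Character vector of ids.
#' @param related_pairs Data frame with columns \code{id1}, \code{id2} (any
#'   extra columns ignored), or NULL/zero rows for no relatedness. Pairs
#'   referencing individuals absent from \code{individual_ids} are ignored,
#'   so the operation is idempotent on its own output.
#' @param seed Integer seed for the random simple-pair rule.
#' @return Character vector of retained ids (original order preserved).
#' @examples
#' select_unrelated(c("A", "B", "C"),
#'                  data.frame(id1 = c("A", "A"), id2 = c("B", "C")))
#' @export
select_unrelated <- function(individual_ids, related_pairs, seed = 1L) {
  ids <- as.character(individual_ids)
  if (is.null(related_pairs) || nrow(related_pairs) == 0L) return(ids)
  a <- as.character(related_pairs$id1)
  b <- as.character(related_pairs$id2)
  if (any(a == b)) stop("self-pairs are not valid kinship records", call. = FALSE)
  # pairs involving individuals outside the supplied set carry no
  # constraint here; ignoring them makes the operation idempotent
  inset <- a %in% ids & b %in% ids
  a <- a[inset]; b <- b[inset]
  if (!length(a)) return(ids)
  # drop duplicate undirected edges
  key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  keep_edge <- !duplicated(key)
  a <- a[keep_edge]; b <- b[keep_edge]

  set.seed(child_seed(seed, .seed_offsets[["unrelated"]]))
  removed <- character(0)
  alive_edge <- rep(TRUE, length(a))
  repeat {
    ae <- which(alive_edge)
    if (!length(ae)) break
    deg <- table(c(a[ae], b[ae]))
    dmax <- max(deg)
    cand <- sort(names(deg)[deg == dmax])
    if (dmax == 1) {
      # only simple pairs remain: take the first pair, drop one at random
      e <- ae[1L]
      drop_id <- sample(c(a[e], b[e]), 1L)
    } else {
      drop_id <- cand[1L]
    }
    removed <- c(removed, drop_id)
    alive_edge[a == drop_id | b == drop_id] <- FALSE
  }
  ids[!ids %in% removed]
}

#' Filter variants on imputation quality, minor-allele frequency and
#' exposure association
#'
#' Retains variants with INFO at or above \code{info_min}, minor-allele
#' frequency (computed as \code{min(eaf, 1 - eaf)}) at or above
#' \code{maf_min}, and exposure p-value strictly below \code{p_max};
#' exclusion is strict on the stated thresholds (INFO < 0.9 or MAF < 0.1\%
#' excluded; genome-wide significance requires p < 5e-8). Input order is
#' preserved.
#'
#' @param variants Data frame with columns \code{variant_id}, \code{eaf},
#'   \code{info} and \code{p_exposure} (or \code{p}).
#' @param info_min Minimum imputation quality (default 0.9).
#' @param maf_min Minimum minor-allele frequency (default 0.001).
#' @param p_max Exclusive p-value ceiling (default 5e-8).
#' @return The retained rows of \code{variants}.
#' @export
filter_variants <- function(variants, info_min = 0.9, maf_min = 0.001,
                            p_max = 5e-8) {
  pcol <- if ("p_exposure" %in% names(variants)) "p_exposure" else "p"
  need <- c("variant_id", "eaf", "info", pcol)
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  eaf <- variants$eaf; info <- variants$info; p <- variants[[pcol]]
  bad <- !is.finite(eaf) | eaf <= 0 | eaf >= 1 | !is.finite(info) |
    info < 0 | info > 1 | !is.finite(p)
  if (any(bad)) {
    stop("malformed variant records: ",
         paste(utils::head(variants$variant_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  maf <- pmin(eaf, 1 - eaf)
  variants[info >= info_min & maf >= maf_min & p < p_max, , drop = FALSE]
}

#' Read a tab-separated variant table
#'
#' Expected header: \code{variant_id}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{info}, \code{p} (or
#' \code{p_exposure}).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_variant_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
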