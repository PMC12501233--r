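# Enrichment filtering of label-free quantification (LFQ) intensity tables:
# QC by peptide count / sequence coverage / replicate detection, then
# classification into exclusive / up / down / unchanged between the
# serum-starved (SS) and serum-fed (+S) conditions.
#
# An LFQ table is a data frame with columns
#   protein_id, ss_1, ss_2, ss_3, s_1, s_2, s_3, peptides, coverage
# where the six intensity columns are the triplicate replicates of each
# condition. Missing detections are NA internally; an intensity of exactly 0
# is also treated as missing (the usual LFQ output convention), controlled by
# `zero_as_missing` in the readers.

.lfq_cols <- c("protein_id", "ss_1", "ss_2", "ss_3", "s_1", "s_2", "s_3",
               "peptides", "coverage")

.check_lfq <- function(lfq) {
  if (!is.data.frame(lfq)) stop("LFQ input must be a data frame")
  missing <- setdiff(.lfq_cols, names(lfq))
  if (length(missing)) {
    stop("LFQ table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(lfq$protein_id)) {
    stop("duplicate protein_id in LFQ table: ",
         paste(unique(lfq$protein_id[duplicated(lfq$protein_id)]),
               collapse = ", "))
  }
  invisible(lfq)
}

.valid_intensity <- function(x) !is.na(x) & x > 0

#' Quality-control filter for LFQ records
#'
#' A protein passes QC iff it was identified with at least `min_peptides`
#' peptides, at least `min_coverage` percent sequence coverage, and detected
#' (non-missing intensity) in at least `min_replicates` of the 3 replicates
#' of at least one condition.
#'
#' @param lfq LFQ data frame (see [classify_proteins()] for the schema).
#' @param min_peptides,min_coverage,min_replicates QC thresholds (defaults 2
#'   peptides, 10 percent, 2 of 3 replicates).
#' @return Logical vector, one element per row.
#' @export
#' @examples
#' lfq <- data.frame(protein_id = "P1", ss_1 = 100, ss_2 = 110, ss_3 = NA,
#'                   s_1 = NA, s_2 = NA, s_3 = NA, peptides = 2, coverage = 10)
#' qc_filter(lfq)  # TRUE: boundary of every rule
qc_filter <- function(lfq, min_peptides = 2, min_coverage = 10,
                      min_replicates = 2) {
  .check_lfq(lfq)
  n_ss <- .valid_intensity(lfq$ss_1) + .valid_intensity(lfq$ss_2) +
    .valid_intensity(lfq$ss_3)
  n_s <- .valid_intensity(lfq$s_1) + .valid_intensity(lfq$s_2) +
    .valid_intensity(lfq$s_3)
  lfq$peptides >= min_peptides & lfq$coverage >= min_coverage &
    (n_ss >= min_replicates | n_s >= min_replicates)
}

#' Classify proteins as exclusive, up-, down-regulated or unchanged
#'
#' Applies the enrichment-filter rules to each LFQ record:
#' \itemize{
#'   \item records failing [qc_filter()] are `not_evaluable`;
#'   \item detected in >= 2 of 3 SS replicates and 0 of 3 +S replicates:
#'     `exclusive_SS` (mirror rule for `exclusive_S`); exclusives carry no
#'     fold change or p-value;
#'   \item otherwise the fold change is the ratio of means of valid
#'     intensities (SS over +S; raw means by default, matching the
#'     ">2-fold change" convention, with a log-mean option) and the p-value
#'     a two-sided Welch test on log2 valid intensities: `up_SS` iff
#'     FC > `fc_up` and p < `alpha`; `down_SS` iff FC < `fc_down` and
#'     p < `alpha`; else `unchanged`;
#'   \item records with fewer than 2 valid replicates in either condition
#'     (outside the exclusivity rule) cannot be tested: `not_evaluable`
#'     with a reason.
#' }
#' Categories are mutually exclusive and exhaustive over QC-passing records.
#' No multiple-testing correction is applied by default (pass the calls to
#' [stats::p.adjust()] if one is wanted).
#'
#' @param lfq LFQ data frame with columns `protein_id`, `ss_1..ss_3`,
#'   `s_1..s_3`, `peptides`, `coverage`; missing detections as `NA`.
#' @param fc_up,fc_down Fold-change thresholds (defaults 2 and 0.5).
#' @param alpha Significance level of the Welch test (default 0.05).
#' @param fc_method `"raw_means"` (default) or `"log_means"` (geometric).
#' @inheritParams qc_filter
#' @return Data frame of calls: `protein_id`, `qc_pass`, `category`,
#'   `fold_change`, `p_value`, `reason`.
#' @export
#' @examples
#' lfq <- data.frame(protein_id = "P1",
#'                   ss_1 = 400, ss_2 = 380, ss_3 = 420,
#'                   s_1 = 100, s_2 = 95, s_3 = 105,
#'                   peptides = 3, coverage = 30)
#' classify_proteins(lfq)   # up_SS at FC 4
classify_proteins <- function(lfq, fc_up = 2, fc_down = 0.5, alpha = 0.05,
                              fc_method = c("raw_means", "log_means"),
                              min_peptides = 2, min_coverage = 10,
                              min_replicates = 2) {
  .check_lfq(lfq)
  fc_method <- match.arg(fc_method)
  qc <- qc_filter(lfq, min_peptides, min_coverage, min_replicates)
  n <- nrow(lfq)
  category <- character(n)
  fold_change <- rep(NA_real_, n)
  p_value <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  ss_mat <- as.matrix(lfq[, c("ss_1", "ss_2", "ss_3")])
  s_mat <- as.matrix(lfq[, c("s_1", "s_2", "s_3")])
  for (i in seq_len(n)) {
    ss <- ss_mat[i, ][.valid_intensity(ss_mat[i, ])]
    s <- s_mat[i, ][.valid_intensity(s_mat[i, ])]
    if (!qc[i]) {
      category[i] <- "not_evaluable"
      reason[i] <- "failed QC"
      next
    }
    if (length(ss) >= min_replicates && length(s) == 0) {
      category[i] <- "exclusive_SS"
      next
    }
    if (length(s) >= min_replicates && length(ss) == 0) {
      category[i] <- "exclusive_S"
      next
    }
    if (length(ss) < 2 || length(s) < 2) {
      category[i] <- "not_evaluable"
      reason[i] <- "fewer than 2 valid replicates in one condition"
      next
    }
    mean_s <- mean(s)
    if (mean_s <= 0) {
      category[i] <- "not_evaluable"
      reason[i] <- "zero mean intensity in +S"
      next
    }
    fc <- if (fc_method == "raw_means") mean(ss) / mean_s
          else 2^(mean(log2(ss)) - mean(log2(s)))
    lss <- log2(ss); ls <- log2(s)
    p <- if (stats::sd(lss) == 0 && stats::sd(ls) == 0) {
      if (mean(lss) == mean(ls)) 1 else 0
    } else {
      stats::t.test(lss, ls, var.equal = FALSE)$p.value
    }
    fold_change[i] <- fc
    p_value[i] <- p
    category[i] <- if (fc > fc_up && p < alpha) "up_SS"
                   else if (fc < fc_down && p < alpha) "down_SS"
                   else "unchanged"
  }
  data.frame(protein_id = lfq$protein_id, qc_pass = qc, category = category,
             fold_change = fold_change, p_value = p_value, reason = reason,
             stringsAsFactors = FALSE)
}

#' SS-enriched protein set
#'
#' The proteins "enriched" under serum starvation: exactly the union of the
#' `exclusive_SS` and `up_SS` calls among QC-passing records. This is the
#' set that downstream pathway analysis consumes.
#'
#' @inheritParams classify_proteins
#' @param ... Further arguments passed to [classify_proteins()].
#' @return Sorted character vector of protein identifiers.
#' @export
enriched_set <- function(lfq, ...) {
  calls <- classify_proteins(lfq, ...)
  sort(calls$protein_id[calls$qc_pass &
                          calls$category %in% c("exclusive_SS", "up_SS")])
}
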