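# Closed-form assay scores: relative mtDNA content from qPCR delta-Ct,
# xenograft tumor volume from calliper measurements, and the tumor
# inhibitory score comparing PKH label-retaining fractions normalized to
# tumor volume between drug regimens.

#' Relative mtDNA content from qPCR cycle thresholds
#'
#' \deqn{\Delta Ct = Ct_{nuclear} - Ct_{mito};\quad
#'   \mathrm{content} = 2 \cdot 2^{\Delta Ct}}
#' The nuclear target anchors the copy number (two copies per diploid
#' genome), so the content is the mtDNA copy number relative to the nuclear
#' genome. Strictly increasing in the nuclear Ct and decreasing in the
#' mitochondrial Ct. Vectorized.
#'
#' @param ct_nuclear,ct_mito Mean cycle thresholds of the nuclear and
#'   mitochondrial targets (cycles); values outside the typical 5-40 range
#'   trigger a warning.
#' @return Positive scalar (or vector) relative content.
#' @export
#' @examples
#' relative_mtdna_content(20, 20)  # delta Ct 0 -> 2
#' relative_mtdna_content(20, 15)  # delta Ct 5 -> 64
relative_mtdna_content <- function(ct_nuclear, ct_mito) {
  if (!all(is.finite(ct_nuclear)) || !all(is.finite(ct_mito))) {
    stop("Ct values must be finite")
  }
  if (any(ct_nuclear < 5 | ct_nuclear > 40 | ct_mito < 5 | ct_mito > 40)) {
    warning("Ct value(s) outside the typical 5-40 cycle range")
  }
  2 * 2^(ct_nuclear - ct_mito)
}

#' Relative mtDNA content for a table of qPCR triplicates
#'
#' Aggregates triplicate Ct values per sample (mean by default, matching the
#' convention of computing the score from mean triplicate Cts; set
#' `aggregate = "per_replicate"` to score each replicate pair) and applies
#' [relative_mtdna_content()].
#'
#' @param qpcr Data frame with columns `sample_id`, `replicate`,
#'   `ct_nuclear`, `ct_mito` (long format, one row per replicate).
#' @param aggregate `"mean"` or `"per_replicate"`.
#' @return Data frame with `sample_id` (and `replicate` in per-replicate
#'   mode), `ct_nuclear`, `ct_mito`, `delta_ct`, `relative_content`.
#' @export
qpcr_relative_content <- function(qpcr, aggregate = c("mean", "per_replicate")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample_id", "replicate", "ct_nuclear", "ct_mito")
  missing <- setdiff(need, names(qpcr))
  if (length(missing)) {
    stop("qPCR table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (aggregate == "mean") {
    agg <- stats::aggregate(cbind(ct_nuclear, ct_mito) ~ sample_id,
                            data = qpcr, FUN = mean)
  } else {
    agg <- qpcr[, need]
  }
  agg$delta_ct <- agg$ct_nuclear - agg$ct_mito
  agg$relative_content <- relative_mtdna_content(agg$ct_nuclear, agg$ct_mito)
  agg
}

#' Xenograft tumor volume
#'
#' \deqn{V = 0.5 \times \mathrm{length} \times \mathrm{width}^2} in cubic
#' millimetres from calliper length and width in millimetres. Vectorized.
#'
#' @param length,width Tumor dimensions (mm, > 0).
#' @return Volume (mm^3).
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(length, width) {
  if (!all(is.finite(length) & length > 0) ||
      !all(is.finite(width) & width > 0)) {
    stop("tumor length and width must be finite and > 0")
  }
  0.5 * length * width^2
}

#' A single xenograft record
#'
#' @param group Drug-regimen label.
#' @param pkh_hi,pkh_lo Percentages of the PKH26-high (quiescent/CSC) and
#'   PKH26-low (progenitor) label-retaining fractions; each in \[0, 100\]
#'   and jointly at most 100.
#' @param tumor_length,tumor_width Calliper dimensions (mm), used to derive
#'   the volume when `tumor_volume` is not given.
#' @param tumor_volume Volume (mm^3, > 0); derived from the dimensions when
#'   `NULL`.
#' @return Object of class `xenograft_record` (a one-row data frame).
#' @export
xenograft_record <- function(group, pkh_hi, pkh_lo,
                             tumor_length = NULL, tumor_width = NULL,
                             tumor_volume = NULL) {
  if (pkh_hi < 0 || pkh_hi > 100 || pkh_lo < 0 || pkh_lo > 100) {
    stop("PKH fractions must be percentages in [0, 100]")
  }
  if (pkh_hi + pkh_lo > 100) {
    stop("pkh_hi + pkh_lo must be <= 100 (they are disjoint fractions)")
  }
  if (is.null(tumor_volume)) {
    if (is.null(tumor_length) || is.null(tumor_width)) {
      stop("supply either tumor_volume or both tumor_length and tumor_width")
    }
    tumor_volume <- tumor_volume(tumor_length, tumor_width)
  }
  if (!is.finite(tumor_volume) || tumor_volume <= 0) {
    stop("tumor volume must be > 0 for score computation")
  }
  structure(data.frame(group = group, pkh_hi = pkh_hi, pkh_lo = pkh_lo,
                       tumor_length = if (is.null(tumor_length)) NA_real_ else tumor_length,
                       tumor_width = if (is.null(tumor_width)) NA_real_ else tumor_width,
                       tumor_volume = tumor_volume,
                       stringsAsFactors = FALSE),
            class = c("xenograft_record", "data.frame"))
}

#' Tumor inhibitory score
#'
#' Compares the volume-normalized label-retaining burden between a vehicle
#' control and a treated tumor:
#' \deqn{\mathrm{score} =
#'   \frac{\%PKH^{hi}_C + \%PKH^{lo}_C}{V_C} -
#'   \frac{\%PKH^{hi}_T + \%PKH^{lo}_T}{V_T}}
#' A higher score reflects a more effective reduction of the
#' slow-cycling/quiescent tumor fraction by the treatment. The formula gives
#' 0 when test equals control; `anchored = TRUE` adds 1 so the control maps
#' to a displayed score of 1 (a labelled display convention, not a change to
#' the formula).
#'
#' @param control,test [xenograft_record()] objects (or one-row data frames
#'   with `pkh_hi`, `pkh_lo`, `tumor_volume`).
#' @param anchored Report the control-anchored display score (`score + 1`).
#' @return Signed scalar score.
#' @export
#' @examples
#' ctl <- xenograft_record("vehicle", 5, 20, tumor_volume = 500)
#' trt <- xenograft_record("doxy", 10, 25, tumor_volume = 100)
#' tumor_inhibitory_score(ctl, trt)  # 25/500 - 35/100 = -0.30
tumor_inhibitory_score <- function(control, test, anchored = FALSE) {
  term <- function(r) {
    if (!all(c("pkh_hi", "pkh_lo", "tumor_volume") %in% names(r))) {
      stop("records need pkh_hi, pkh_lo and tumor_volume")
    }
    v <- r$tumor_volume[1]
    if (!is.finite(v) || v <= 0) stop("tumor volume must be > 0")
    (r$pkh_hi[1] + r$pkh_lo[1]) / v
  }
  score <- term(control) - term(test)
  if (anchored) score + 1 else score
}

#' Score every regimen of a xenograft cohort against the vehicle control
#'
#' Aggregates each group (mean PKH fractions and mean volume) and computes
#' [tumor_inhibitory_score()] of the control group versus each other group.
#'
#' @param cohort Data frame of xenograft records (columns `group`, `pkh_hi`,
#'   `pkh_lo`, `tumor_volume`).
#' @param control_group Label of the vehicle-control group.
#' @param anchored Passed to [tumor_inhibitory_score()].
#' @return Data frame `group`, `score`, ordered by decreasing score; the
#'   control group scores 0 (or 1 when anchored) by construction.
#' @export
score_cohort <- function(cohort, control_group = "vehicle", anchored = FALSE) {
  if (!control_group %in% cohort$group) {
    stop("control group '", control_group, "' not present in cohort")
  }
  agg <- stats::aggregate(cbind(pkh_hi, pkh_lo, tumor_volume) ~ group,
                          data = cohort, FUN = mean)
  ctl <- agg[agg$group == control_group, ]
  scores <- vapply(seq_len(nrow(agg)), function(i) {
    tumor_inhibitory_score(ctl, agg[i, ], anchored = anchored)
  }, numeric(1))
  out <- data.frame(group = agg$group, score = scores,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$group), , drop = FALSE]
}
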