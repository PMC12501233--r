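# Seeded generators for every input the pipeline consumes: LFQ intensity
# tables with planted enrichment truth, qPCR Ct triplicates around a known
# copy ratio, xenograft cohorts with planted regimen effects, and
# multiplicative perturbations of the model preset table. A single spec seed
# fans out to fixed per-stream substreams so each stage is independently
# reproducible.

#' Specification for the synthetic-data generators
#'
#' @param seed Integer master seed; each generator derives its own fixed
#'   substream from it.
#' @param n_proteins Number of proteins in the LFQ table.
#' @param n_exclusive_ss,n_up_ss,n_down_ss,n_exclusive_s Planted counts per
#'   category; the remainder is unchanged background. Counts must sum to at
#'   most `n_proteins`.
#' @param lfq_mean_log2,lfq_protein_sd Log2-scale location and
#'   between-protein spread of baseline intensities.
#' @param lfq_replicate_sd Log2-scale replicate noise (0.2 by default: well
#'   separated from the planted two-log2-unit shifts, so the planted
#'   categories are recoverable exactly).
#' @param log2fc_up,log2fc_down Planted log2 fold changes (defaults +2 and
#'   -2, i.e. FC 4 and 0.25, far from the 2 / 0.5 call thresholds).
#' @param missing_rate Probability that a background replicate intensity is
#'   missing. Default 0; at high rates a background protein can by chance
#'   match the exclusivity rule while its truth stays "unchanged".
#' @param qpcr_n,qpcr_true_delta_ct,qpcr_ct_sd,qpcr_ct_nuclear_mean Number
#'   of qPCR samples, true delta-Ct (nuclear minus mitochondrial), Gaussian
#'   Ct noise SD (cycles), and nuclear-target mean Ct.
#' @param xeno_groups Data frame of group-level means: `group`, `n`,
#'   `pkh_hi`, `pkh_lo`, `length`, `width`. The defaults plant a monotone
#'   inhibition gradient: each successive regimen lowers both the tumor
#'   volume and the volume-normalized label-retaining burden, so the
#'   combination regimen ranks first under the tumor inhibitory score.
#' @param xeno_pkh_sd,xeno_dim_sd Gaussian SDs of the PKH percentages
#'   (percent points) and calliper dimensions (mm); draws are truncated to
#'   the valid ranges.
#' @param preset_cv Coefficient of variation for [perturb_presets()].
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_proteins = 200L,
                           n_exclusive_ss = 20L, n_up_ss = 30L,
                           n_down_ss = 30L, n_exclusive_s = 0L,
                           lfq_mean_log2 = 25, lfq_protein_sd = 2,
                           lfq_replicate_sd = 0.2,
                           log2fc_up = 2, log2fc_down = -2,
                           missing_rate = 0,
                           qpcr_n = 12L, qpcr_true_delta_ct = 2,
                           qpcr_ct_sd = 0.1, qpcr_ct_nuclear_mean = 24,
                           xeno_groups = default_xeno_groups(),
                           xeno_pkh_sd = 0.5, xeno_dim_sd = 0.5,
                           preset_cv = 0.05) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  counts <- c(n_exclusive_ss, n_up_ss, n_down_ss, n_exclusive_s)
  if (any(counts < 0) || sum(counts) > n_proteins) {
    stop("planted counts must be >= 0 and sum to at most n_proteins")
  }
  sds <- c(lfq_protein_sd, lfq_replicate_sd, qpcr_ct_sd, xeno_pkh_sd,
           xeno_dim_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]")
  }
  if (preset_cv < 0) stop("preset_cv must be >= 0")
  stopifnot(is.data.frame(xeno_groups),
            all(c("group", "n", "pkh_hi", "pkh_lo", "length", "width") %in%
                  names(xeno_groups)))
  structure(list(seed = seed, n_proteins = as.integer(n_proteins),
                 n_exclusive_ss = as.integer(n_exclusive_ss),
                 n_up_ss = as.integer(n_up_ss),
                 n_down_ss = as.integer(n_down_ss),
                 n_exclusive_s = as.integer(n_exclusive_s),
                 lfq_mean_log2 = lfq_mean_log2,
                 lfq_protein_sd = lfq_protein_sd,
                 lfq_replicate_sd = lfq_replicate_sd,
                 log2fc_up = log2fc_up, log2fc_down = log2fc_down,
                 missing_rate = missing_rate,
                 qpcr_n = as.integer(qpcr_n),
                 qpcr_true_delta_ct = qpcr_true_delta_ct,
                 qpcr_ct_sd = qpcr_ct_sd,
                 qpcr_ct_nuclear_mean = qpcr_ct_nuclear_mean,
                 xeno_groups = xeno_groups,
                 xeno_pkh_sd = xeno_pkh_sd, xeno_dim_sd = xeno_dim_sd,
                 preset_cv = preset_cv),
            class = "generator_spec")
}

#' @describeIn generator_spec Default xenograft group-mean table: a vehicle
#'   control plus four regimens of increasing planted inhibition.
#' @export
default_xeno_groups <- function() {
  data.frame(
    group = c("vehicle", "doxycycline", "erythromycin", "doxy_pax", "ery_pax"),
    n = c(5L, 5L, 5L, 5L, 5L),
    pkh_hi = c(8, 5, 4, 3, 1.5),
    pkh_lo = c(25, 16, 13, 9, 5),
    length = c(12, 10.5, 10, 9.5, 9),
    width = c(10, 9, 8.5, 8, 7.5),
    stringsAsFactors = FALSE)
}

# Run `expr` under a fixed substream of the master seed without disturbing
# the caller's RNG state.
.with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Generate an LFQ intensity table with planted ground truth
#'
#' Baseline log2 intensities are drawn per protein, replicate intensities
#' log-normally around them, and the planted categories shifted by the
#' spec's log2 fold changes; exclusives are generated with the opposite
#' condition entirely missing. Peptide counts and coverage are drawn above
#' the QC thresholds so planted records always pass the QC rule. Planted
#' positions are shuffled (deterministically under the seed).
#'
#' @param spec A [generator_spec()].
#' @return List with `lfq` (the intensity table, `NA` for missing) and
#'   `truth` (data frame `protein_id`, `category`).
#' @export
#' @examples
#' synth <- make_lfq_table(generator_spec(seed = 7))
#' table(synth$truth$category)
make_lfq_table <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .with_substream(spec$seed, 101L, {
    n <- spec$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    cats <- rep("unchanged", n)
    planted <- c(rep("exclusive_SS", spec$n_exclusive_ss),
                 rep("up_SS", spec$n_up_ss),
                 rep("down_SS", spec$n_down_ss),
                 rep("exclusive_S", spec$n_exclusive_s))
    pos <- sample(n, length(planted))
    cats[pos] <- planted
    base <- stats::rnorm(n, spec$lfq_mean_log2, spec$lfq_protein_sd)
    shift <- ifelse(cats == "up_SS", spec$log2fc_up,
                    ifelse(cats == "down_SS", spec$log2fc_down, 0))
    draw <- function(mu) 2^(mu + stats::rnorm(length(mu), 0, spec$lfq_replicate_sd))
    ss <- sapply(1:3, function(k) draw(base + shift))
    s <- sapply(1:3, function(k) draw(base))
    ss[cats == "exclusive_S", ] <- NA_real_
    s[cats == "exclusive_SS", ] <- NA_real_
    if (spec$missing_rate > 0) {
      bg <- cats == "unchanged"  # MCAR dropout on background records only
      drop_ss <- bg & matrix(stats::runif(n * 3) < spec$missing_rate, n, 3)
      drop_s <- bg & matrix(stats::runif(n * 3) < spec$missing_rate, n, 3)
      ss[drop_ss] <- NA_real_
      s[drop_s] <- NA_real_
    }
    lfq <- data.frame(protein_id = ids,
                      ss_1 = ss[, 1], ss_2 = ss[, 2], ss_3 = ss[, 3],
                      s_1 = s[, 1], s_2 = s[, 2], s_3 = s[, 3],
                      peptides = sample(2:15, n, replace = TRUE),
                      coverage = round(stats::runif(n, 10, 60), 1),
                      stringsAsFactors = FALSE)
    list(lfq = lfq,
         truth = data.frame(protein_id = ids, category = cats,
                            stringsAsFactors = FALSE))
  })
}

#' Generate qPCR Ct triplicates with a known copy ratio
#'
#' Nuclear-target Cts are drawn around the spec's nuclear mean and
#' mitochondrial-target Cts around (nuclear mean - true delta-Ct), both with
#' Gaussian cycle noise, in triplicate per sample.
#'
#' @param spec A [generator_spec()].
#' @return Long data frame `sample_id`, `replicate`, `ct_nuclear`,
#'   `ct_mito`, with attribute `"truth"` carrying the true delta-Ct and true
#'   relative content.
#' @export
make_qpcr <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .with_substream(spec$seed, 202L, {
    n <- spec$qpcr_n
    df <- data.frame(
      sample_id = rep(sprintf("S%03d", seq_len(n)), each = 3),
      replicate = rep(1:3, n),
      ct_nuclear = stats::rnorm(3 * n, spec$qpcr_ct_nuclear_mean,
                                spec$qpcr_ct_sd),
      ct_mito = stats::rnorm(3 * n,
                             spec$qpcr_ct_nuclear_mean - spec$qpcr_true_delta_ct,
                             spec$qpcr_ct_sd),
      stringsAsFactors = FALSE)
    attr(df, "truth") <- list(
      true_delta_ct = spec$qpcr_true_delta_ct,
      true_relative_content = 2 * 2^spec$qpcr_true_delta_ct)
    df
  })
}

#' Generate a xenograft cohort with planted regimen effects
#'
#' Per-animal PKH fractions and calliper dimensions are Gaussian around the
#' spec's group means, truncated to valid ranges (percentages to \[0, 100\]
#' with `pkh_hi + pkh_lo <= 100`, dimensions to > 0); volume is derived via
#' [tumor_volume()].
#'
#' @param spec A [generator_spec()].
#' @return Data frame of animals (`group`, `animal`, `pkh_hi`, `pkh_lo`,
#'   `tumor_length`, `tumor_width`, `tumor_volume`) with attribute
#'   `"truth"`: the group-mean table extended with the expected (noise-free)
#'   volume and tumor inhibitory score per group.
#' @export
make_xenograft_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .with_substream(spec$seed, 303L, {
    g <- spec$xeno_groups
    rows <- NULL
    for (i in seq_len(nrow(g))) {
      for (a in seq_len(g$n[i])) {
        hi <- min(100, max(0, stats::rnorm(1, g$pkh_hi[i], spec$xeno_pkh_sd)))
        lo <- min(100 - hi, max(0, stats::rnorm(1, g$pkh_lo[i], spec$xeno_pkh_sd)))
        len <- max(0.5, stats::rnorm(1, g$length[i], spec$xeno_dim_sd))
        wid <- max(0.5, stats::rnorm(1, g$width[i], spec$xeno_dim_sd))
        rows <- rbind(rows, data.frame(
          group = g$group[i], animal = sprintf("%s_%d", g$group[i], a),
          pkh_hi = hi, pkh_lo = lo, tumor_length = len, tumor_width = wid,
          tumor_volume = tumor_volume(len, wid), stringsAsFactors = FALSE))
      }
    }
    truth <- g
    truth$tumor_volume <- tumor_volume(g$length, g$width)
    ctl <- truth[truth$group == "vehicle", ]
    if (nrow(ctl) == 1) {
      truth$expected_score <- vapply(seq_len(nrow(truth)), function(i) {
        tumor_inhibitory_score(ctl, truth[i, ])
      }, numeric(1))
    }
    attr(rows, "truth") <- truth
    rows
  })
}

#' Perturb the model preset table multiplicatively
#'
#' Applies mean-one log-normal noise with coefficient of variation `cv` to
#' the structural and OPA1/DRP1 columns of a preset table; used to probe the
#' robustness of the model's qualitative claims to measurement uncertainty.
#' `cv = 0` returns the base table unchanged; `NA` cells stay `NA`; all
#' fields remain non-negative by construction.
#'
#' @param presets Preset data frame (see [load_presets()]).
#' @param cv Coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @return Perturbed preset data frame.
#' @export
perturb_presets <- function(presets, cv, seed = 1L) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(presets)
  .with_substream(as.integer(seed), 404L, {
    sdlog <- sqrt(log1p(cv^2))
    meanlog <- -sdlog^2 / 2
    for (cl in c("c_w", "c_n", "c_jw", "m_p", "opa1", "drp1")) {
      fac <- stats::rlnorm(nrow(presets), meanlog, sdlog)
      presets[[cl]] <- presets[[cl]] * fac
    }
    presets
  })
}
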