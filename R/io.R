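# CSV readers/writers for every table the pipeline exchanges, plus JSON
# provenance sidecars. All writers are deterministic (no timestamps) so a
# rerun with identical inputs is byte-identical; all readers validate the
# schema strictly and name offending rows/columns.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a trajectory as CSV with a JSON provenance sidecar
#'
#' The CSV has columns `time, n_hu, n_du, n_hf, n_df, atp`; the sidecar
#' `<path>.json` records the scenario (cell line, condition, structural
#' parameters, OPA1/DRP1), the full constants, the solver settings, the
#' diagnostics and the package version — everything needed to regenerate the
#' CSV. Sidecars carry no timestamps, so reruns are byte-identical.
#'
#' @param traj A `mito_trajectory`.
#' @param path Output CSV path.
#' @param sidecar Write the provenance sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "mito_trajectory"))
  .write_csv(as.data.frame(traj), path)
  if (sidecar) {
    sc <- traj$scenario
    prov <- list(
      package = "mitodyn",
      version = as.character(utils::packageVersion("mitodyn")),
      scenario = list(cell_line = sc$cell_line, condition = sc$condition,
                      structural = unclass(sc$structural),
                      opa1 = sc$opa1, drp1 = sc$drp1,
                      constants = unclass(sc$constants)),
      settings = unclass(traj$settings),
      diagnostics = traj$diagnostics)
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param must_sidecar Error when the sidecar is absent (it carries the
#'   scenario; without it only times/states are recovered).
#' @return `read_trajectory()`: a `mito_trajectory` (scenario and settings
#'   restored from the sidecar when present).
#' @export
read_trajectory <- function(path, must_sidecar = FALSE) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8-BOM")
  need <- c("time", .state_cols)
  if (!identical(names(df), need)) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  }
  side <- paste0(path, ".json")
  scenario <- NULL
  settings <- NULL
  if (file.exists(side)) {
    prov <- jsonlite::read_json(side, simplifyVector = TRUE)
    st <- prov$scenario$structural
    cs <- prov$scenario$constants
    scenario <- scenario_params(
      prov$scenario$cell_line, prov$scenario$condition,
      structural_params(st$c_w, st$c_n, st$c_jw, st$m_p),
      opa1 = prov$scenario$opa1, drp1 = prov$scenario$drp1,
      constants = dynamics_constants(
        F_0 = cs$F_0, K_0 = cs$K_0, M_H = cs$M_H, M_D = cs$M_D,
        alpha = cs$alpha, epsilon = cs$epsilon, mu = cs$mu,
        stress = cs$stress, biogenesis_mode = cs$biogenesis_mode,
        B_const = cs$B_const),
      allow_zero_stress = TRUE)
    sg <- prov$settings
    settings <- solver_settings(
      t_start = sg$t_start, t_end = sg$t_end, method = sg$method,
      rtol = sg$rtol, atol = sg$atol, dt = sg$dt, n_out = sg$n_out,
      negativity_policy = sg$negativity_policy,
      atp_floor_policy = sg$atp_floor_policy, clip_tol = sg$clip_tol,
      blowup_cap = sg$blowup_cap)
  } else if (must_sidecar) {
    stop("provenance sidecar not found: ", side)
  }
  .new_trajectory(df$time, as.matrix(df[, .state_cols]), scenario, settings)
}

#' Write / read an LFQ intensity table
#'
#' The on-disk dialect stores missing detections as intensity 0 (the usual
#' LFQ output convention); `zero_as_missing` converts them to `NA` on read
#' and back to 0 on write.
#'
#' @param lfq LFQ data frame (`NA` for missing).
#' @param path CSV (or TSV, by extension) path.
#' @param zero_as_missing Treat stored zeros as missing detections.
#' @return `path` invisibly / the LFQ data frame.
#' @export
write_lfq <- function(lfq, path, zero_as_missing = TRUE) {
  .check_lfq(lfq)
  out <- lfq
  if (zero_as_missing) {
    for (cl in c("ss_1", "ss_2", "ss_3", "s_1", "s_2", "s_3")) {
      out[[cl]][is.na(out[[cl]])] <- 0
    }
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lfq
#' @export
read_lfq <- function(path, zero_as_missing = TRUE) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  lfq <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8-BOM")
  .check_lfq(lfq)
  for (cl in c("ss_1", "ss_2", "ss_3", "s_1", "s_2", "s_3",
               "peptides", "coverage")) {
    if (!is.numeric(lfq[[cl]])) {
      stop("LFQ column '", cl, "' is not numeric; offending row(s): ",
           paste(which(is.na(suppressWarnings(as.numeric(lfq[[cl]])))),
                 collapse = ", "))
    }
    if (zero_as_missing && cl %in% c("ss_1", "ss_2", "ss_3",
                                     "s_1", "s_2", "s_3")) {
      lfq[[cl]][lfq[[cl]] == 0] <- NA_real_
    }
  }
  lfq
}

#' Write enrichment calls and the enriched-set list
#'
#' @param calls Calls data frame from [classify_proteins()].
#' @param ids Character vector of enriched protein ids.
#' @param path Output path (CSV for calls, plain text one id per line for
#'   the set).
#' @return `path`, invisibly.
#' @export
write_enrichment_calls <- function(calls, path) {
  .write_csv(calls, path)
  invisible(path)
}

#' @rdname write_enrichment_calls
#' @export
write_enriched_set <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Write / read qPCR and xenograft tables
#'
#' Plain CSV with strict schemas: qPCR tables carry `sample_id, replicate,
#' ct_nuclear, ct_mito`; xenograft tables `group, animal, pkh_hi, pkh_lo,
#' tumor_length, tumor_width, tumor_volume`.
#'
#' @param df Table to write.
#' @param path CSV path.
#' @return `path` invisibly / the validated data frame.
#' @export
write_qpcr <- function(df, path) {
  .write_csv(df[, c("sample_id", "replicate", "ct_nuclear", "ct_mito")], path)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  need <- c("sample_id", "replicate", "ct_nuclear", "ct_mito")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("qPCR CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' @rdname write_qpcr
#' @export
write_xenografts <- function(df, path) {
  .write_csv(df[, c("group", "animal", "pkh_hi", "pkh_lo", "tumor_length",
                    "tumor_width", "tumor_volume")], path)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_xenografts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  need <- c("group", "pkh_hi", "pkh_lo", "tumor_volume")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("xenograft CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(df$pkh_hi < 0 | df$pkh_hi > 100 | df$pkh_lo < 0 |
                 df$pkh_lo > 100 | df$pkh_hi + df$pkh_lo > 100 |
                 df$tumor_volume <= 0)
  if (length(bad)) {
    stop("xenograft CSV: invalid PKH fractions or volume in row(s): ",
         paste(bad, collapse = ", "))
  }
  df
}
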