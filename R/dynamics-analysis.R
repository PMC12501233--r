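# Qualitative readouts of the dynamics model: class dominance, unfused
# depletion, SS-vs-+S ATP contrasts, phenotype orderings, and robustness
# sweeps over the free constants.

.nearest_index <- function(traj, t) {
  rng <- range(traj$times)
  if (t < rng[1] || t > rng[2]) {
    stop("time ", format(t), " outside trajectory span [", format(rng[1]),
         ", ", format(rng[2]), "]")
  }
  which.min(abs(traj$times - t))
}

#' State of a trajectory at (nearest to) a requested time
#'
#' @param traj A `mito_trajectory`.
#' @param t Requested time; must lie within the trajectory span. The nearest
#'   stored sample is used (no extrapolation, no silent interpolation).
#' @return Named numeric state vector with attribute `"time"` (the stored
#'   time actually used).
#' @export
state_at <- function(traj, t) {
  i <- .nearest_index(traj, t)
  out <- traj$states[i, ]
  attr(out, "time") <- traj$times[i]
  out
}

#' Unfused fraction of the mitochondrial pool
#'
#' Fraction \eqn{(N_{HU}+N_{DU})/N_{tot}} at the stored time nearest `t`;
#' the model predicts this to collapse under serum starvation as fusion
#' outpaces fission ("unfused depletion"). Defined as 0 when the total is 0.
#'
#' @inheritParams state_at
#' @return Fraction in \[0, 1\].
#' @export
unfused_depletion <- function(traj, t) {
  s <- state_at(traj, t)
  total <- s[["n_hu"]] + s[["n_du"]] + s[["n_hf"]] + s[["n_df"]]
  if (total <= 0) return(0)
  (s[["n_hu"]] + s[["n_du"]]) / total
}

#' ATP contrast between serum-starved and serum-fed trajectories
#'
#' Signed difference and ratio of ATP at time `t` between the SS and +S
#' trajectories of the same cell line.
#'
#' @param traj_ss,traj_s Trajectories of the same cell line (typically the
#'   SS and +S members of a panel).
#' @param t Comparison time (within both spans).
#' @return List with `difference` (ATP_SS - ATP_+S), `ratio`
#'   (ATP_SS / ATP_+S, `NA` when the denominator is 0) and `ratio_defined`.
#' @export
atp_contrast <- function(traj_ss, traj_s, t) {
  if (!identical(traj_ss$scenario$cell_line, traj_s$scenario$cell_line)) {
    stop("ATP contrast requires trajectories of the same cell line, got '",
         traj_ss$scenario$cell_line, "' and '", traj_s$scenario$cell_line, "'")
  }
  a_ss <- state_at(traj_ss, t)[["atp"]]
  a_s <- state_at(traj_s, t)[["atp"]]
  list(difference = a_ss - a_s,
       ratio = if (a_s == 0) NA_real_ else a_ss / a_s,
       ratio_defined = a_s != 0)
}

#' Summarise a panel of trajectories
#'
#' Computes, for each scenario, the state at time `t` (default: end of the
#' trajectory) together with the derived metrics read off the model: HF
#' count, unfused fraction, total count and ATP; plus the full time series
#' of class fractions.
#'
#' @param panel A `mito_panel` from [run_panel()].
#' @param t Read-off time; default the common trajectory end.
#' @return Object of class `mito_panel_summary`: `$metrics` (one row per
#'   scenario), `$fractions` (list of per-scenario data frames of class
#'   fractions over time), `$t`.
#' @export
panel_summary <- function(panel, t = NULL) {
  stopifnot(inherits(panel, "mito_panel"))
  metrics <- NULL
  fractions <- list()
  for (key in names(panel)) {
    traj <- panel[[key]]
    tt <- if (is.null(t)) traj$times[length(traj$times)] else t
    s <- state_at(traj, tt)
    total <- sum(s[c("n_hu", "n_du", "n_hf", "n_df")])
    metrics <- rbind(metrics, data.frame(
      cell_line = traj$scenario$cell_line,
      condition = traj$scenario$condition,
      time = attr(s, "time"),
      n_hu = s[["n_hu"]], n_du = s[["n_du"]],
      n_hf = s[["n_hf"]], n_df = s[["n_df"]],
      total = total,
      hf_count = s[["n_hf"]],
      unfused_fraction = if (total > 0) (s[["n_hu"]] + s[["n_du"]]) / total else 0,
      atp = s[["atp"]],
      stringsAsFactors = FALSE))
    tot_t <- rowSums(traj$states[, c("n_hu", "n_du", "n_hf", "n_df"), drop = FALSE])
    fr <- traj$states[, c("n_hu", "n_du", "n_hf", "n_df"), drop = FALSE] /
      ifelse(tot_t > 0, tot_t, 1)
    fractions[[key]] <- data.frame(time = traj$times, fr, row.names = NULL)
  }
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, fractions = fractions, t = t),
            class = "mito_panel_summary")
}

#' @export
print.mito_panel_summary <- function(x, ...) {
  cat("<mito_panel_summary>\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Rank phenotypes by a model metric
#'
#' Descending order of the five cell lines by HF count or ATP at the summary
#' time, within one condition. Ties are broken lexicographically by cell-line
#' identifier.
#'
#' @param summary A `mito_panel_summary` covering all five phenotypes for
#'   `condition`.
#' @param metric `"hf_count"` or `"atp"`.
#' @param condition `"+S"` or `"SS"`.
#' @return Character vector of cell lines, best first.
#' @export
rank_phenotypes <- function(summary, metric = c("hf_count", "atp"),
                            condition = c("+S", "SS")) {
  stopifnot(inherits(summary, "mito_panel_summary"))
  metric <- match.arg(metric)
  condition <- match.arg(condition)
  m <- summary$metrics[summary$metrics$condition == condition, , drop = FALSE]
  missing <- setdiff(.mito_cell_lines, m$cell_line)
  if (length(missing)) {
    stop("panel summary incomplete for condition ", condition,
         "; missing phenotype(s): ", paste(missing, collapse = ", "))
  }
  m <- m[order(-m[[metric]], m$cell_line), ]
  m$cell_line
}

#' Sweep the free constants and test the model's qualitative claims
#'
#' The measured panel fixes ultrastructure and OPA1/DRP1 but not the free
#' constants (alpha, epsilon, M_H, M_D, F_0, K_0, stress). This sweep reruns
#' the full panel at each grid point and reports, per point, the metrics the
#' qualitative predictions rest on, with pass/fail flags:
#' `flag_atp_ss_gt_s` (ATP higher under SS than +S for every phenotype),
#' `flag_unfused_depleted_ss` (unfused fraction below `depletion_threshold`
#' under SS for every phenotype) and `flag_hf_rank_plus_s` (OVMZ6 above
#' OVCAR3 by HF count under +S). A `stress` grid column overrides the SS
#' stress level (the +S level stays at `stress_plus_s`), so `stress = 0`
#' collapses SS dynamics onto +S dynamics.
#'
#' @param presets Preset data frame covering the full panel.
#' @param grid Data frame whose columns are a subset of
#'   `alpha, epsilon, M_H, M_D, F_0, K_0, stress`; one panel run per row.
#' @param settings Shared [solver_settings()].
#' @param constants Base constants for fields not in the grid.
#' @param stress_plus_s,stress_ss Per-condition stress defaults (overridden
#'   by a `stress` grid column for SS).
#' @param depletion_threshold Unfused-fraction threshold for the depletion
#'   flag.
#' @return Data frame: the grid columns, `min_atp_difference`,
#'   `min_atp_ratio`, `max_unfused_ss`, the three flags, and `n_diverged`
#'   (scenarios whose integration failed at that point are recorded, not
#'   fatal; flags are `NA` where a needed scenario diverged).
#' @export
sweep_constants <- function(presets, grid, settings = solver_settings(),
                            constants = dynamics_constants(),
                            stress_plus_s = 0, stress_ss = 3,
                            depletion_threshold = 0.05) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  allowed <- c("alpha", "epsilon", "M_H", "M_D", "F_0", "K_0", "stress")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) {
    stop("grid columns must be among ", paste(allowed, collapse = ", "),
         "; unexpected: ", paste(bad, collapse = ", "))
  }
  res <- NULL
  for (g in seq_len(nrow(grid))) {
    cs <- constants
    s_ss <- stress_ss
    for (cl in names(grid)) {
      if (cl == "stress") s_ss <- grid$stress[g] else cs[[cl]] <- grid[[cl]][g]
    }
    lines <- unique(presets$cell_line)
    atp_s <- atp_ss <- unf_ss <- hf_s <- stats::setNames(
      rep(NA_real_, length(lines)), lines)
    n_div <- 0L
    for (line in lines) {
      for (cond in c("+S", "SS")) {
        row <- presets[presets$cell_line == line & presets$condition == cond, ,
                       drop = FALSE]
        if (nrow(row) == 0) next
        traj <- tryCatch(
          integrate_scenario(
            scenario_from_preset(row, constants = cs,
                                 stress_plus_s = stress_plus_s,
                                 stress_ss = s_ss),
            settings = settings),
          error = function(e) NULL)
        if (is.null(traj)) { n_div <- n_div + 1L; next }
        tt <- traj$times[length(traj$times)]
        st <- state_at(traj, tt)
        if (cond == "+S") {
          atp_s[line] <- st[["atp"]]
          hf_s[line] <- st[["n_hf"]]
        } else {
          atp_ss[line] <- st[["atp"]]
          unf_ss[line] <- unfused_depletion(traj, tt)
        }
      }
    }
    diff <- atp_ss - atp_s
    ratio <- ifelse(atp_s > 0, atp_ss / atp_s, NA_real_)
    res <- rbind(res, cbind(
      grid[g, , drop = FALSE],
      data.frame(
        min_atp_difference = if (all(is.na(diff))) NA_real_ else min(diff, na.rm = TRUE),
        min_atp_ratio = if (all(is.na(ratio))) NA_real_ else min(ratio, na.rm = TRUE),
        max_unfused_ss = if (all(is.na(unf_ss))) NA_real_ else max(unf_ss, na.rm = TRUE),
        flag_atp_ss_gt_s = if (anyNA(diff)) NA else all(diff > 0),
        flag_unfused_depleted_ss = if (anyNA(unf_ss)) NA else
          all(unf_ss < depletion_threshold),
        flag_hf_rank_plus_s = if (anyNA(hf_s[c("OVMZ6", "OVCAR3")])) NA else
          unname(hf_s["OVMZ6"] > hf_s["OVCAR3"]),
        n_diverged = n_div)))
  }
  rownames(res) <- NULL
  res
}
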