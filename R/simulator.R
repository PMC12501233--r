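#' Integration settings
#'
#' @param t_start,t_end Time span in model (unitless) time; `t_end >=
#'   t_start`. The default horizon of 10 covers the transient and the
#'   approach to the fused-dominated regime for all packaged presets.
#' @param method `"adaptive_rk"` (Dormand-Prince 4(5) with step control),
#'   `"fixed_rk4"` or `"fixed_euler"`.
#' @param rtol,atol Relative/absolute tolerances for the adaptive method.
#'   The tight defaults keep the balance-mode conservation drift of the total
#'   mitochondrial number below 1e-6 over the default horizon.
#' @param dt Step size for the fixed-step methods.
#' @param n_out Number of stored output points for the adaptive method
#'   (fixed-step methods store every step).
#' @param negativity_policy What to do when integration leaves a population
#'   count slightly negative: `"clip_warn"` (clip at 0; excursions beyond
#'   `clip_tol` in magnitude additionally warn) or `"error"`.
#' @param atp_floor_policy `"floor_zero_warn"` (ATP is floored at 0 inside
#'   the dynamics: the constant consumption `mu` cannot drive it negative) or
#'   `"allow"` (integrate the printed equations verbatim).
#' @param clip_tol Magnitude below which a negative excursion is considered
#'   an ordinary integration artifact and clipped silently.
#' @param blowup_cap Any state component exceeding this magnitude aborts with
#'   a divergence error carrying the last valid time (the linear birth terms
#'   permit unbounded growth in constant-biogenesis mode).
#'
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(t_start = 0, t_end = 10,
                            method = c("adaptive_rk", "fixed_rk4", "fixed_euler"),
                            rtol = 1e-8, atol = 1e-10, dt = 1e-3, n_out = 201,
                            negativity_policy = c("clip_warn", "error"),
                            atp_floor_policy = c("floor_zero_warn", "allow"),
                            clip_tol = 1e-8, blowup_cap = 1e12) {
  method <- match.arg(method)
  negativity_policy <- match.arg(negativity_policy)
  atp_floor_policy <- match.arg(atp_floor_policy)
  if (!is.finite(t_start) || !is.finite(t_end) || t_end < t_start) {
    stop("need finite t_end >= t_start")
  }
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_out < 1) stop("n_out must be >= 1")
  structure(list(t_start = t_start, t_end = t_end, method = method,
                 rtol = rtol, atol = atol, dt = dt, n_out = n_out,
                 negativity_policy = negativity_policy,
                 atp_floor_policy = atp_floor_policy,
                 clip_tol = clip_tol, blowup_cap = blowup_cap),
            class = "solver_settings")
}

.state_cols <- c("n_hu", "n_du", "n_hf", "n_df", "atp")

.new_trajectory <- function(times, states, scenario, settings,
                            diagnostics = list()) {
  colnames(states) <- .state_cols
  structure(list(times = times, states = states, scenario = scenario,
                 settings = settings, diagnostics = diagnostics),
            class = "mito_trajectory")
}

#' @export
print.mito_trajectory <- function(x, ...) {
  n <- length(x$times)
  fin <- x$states[n, ]
  cat(sprintf("<trajectory %s %s>  t in [%g, %g], %d points (%s)\n",
              x$scenario$cell_line, x$scenario$condition,
              x$times[1], x$times[n], n, x$settings$method))
  cat(sprintf("  final state: HU=%.4g DU=%.4g HF=%.4g DF=%.4g ATP=%.4g\n",
              fin[1], fin[2], fin[3], fin[4], fin[5]))
  invisible(x)
}

#' @export
as.data.frame.mito_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, row.names = NULL)
}

#' Integrate one scenario of the dynamics model
#'
#' Solves the five coupled ODEs of [state_derivative()] over the requested
#' time span. The adaptive method is a Dormand-Prince 4(5) Runge-Kutta pair
#' with step-size control (via \pkg{deSolve}); `"fixed_rk4"` and
#' `"fixed_euler"` take uniform steps of `settings$dt`.
#'
#' Population counts are physical, so small negative excursions produced by
#' the integrator are clipped at zero under the default policy; excursions
#' larger than `clip_tol` raise a warning (or an error under the `"error"`
#' policy). ATP is floored at zero by default because the constant
#' consumption term would otherwise drain it below zero, a regime the model
#' does not define. Any component exceeding `blowup_cap` raises a divergence
#' error that names the last valid time.
#'
#' @param scenario A [scenario_params()] object.
#' @param initial Initial [system_state()]; defaults to one mitochondrion per
#'   class and no ATP.
#' @param settings A [solver_settings()] object.
#' @return A `mito_trajectory` object: strictly increasing `times`, a matrix
#'   `states` with one row per time, plus the scenario, settings and clip
#'   diagnostics. Coerce with `as.data.frame()`.
#' @export
#' @examples
#' sc <- scenario_params("A4", "+S", structural_params(0.44, 0.54, 0.63, 0.54),
#'                       opa1 = 0.44, drp1 = 1)
#' tr <- integrate_scenario(sc, settings = solver_settings(t_end = 5))
#' tail(as.data.frame(tr))
integrate_scenario <- function(scenario, initial = default_initial_state(),
                               settings = solver_settings()) {
  stopifnot(inherits(scenario, "scenario_params"),
            inherits(settings, "solver_settings"))
  y0 <- as.numeric(unclass(initial)[.state_cols])
  if (settings$t_end == settings$t_start) {
    return(.new_trajectory(settings$t_start, matrix(y0, nrow = 1),
                           scenario, settings))
  }
  p <- .rhs_params(scenario,
                   atp_floor = settings$atp_floor_policy == "floor_zero_warn")
  func <- function(t, y, parms) list(.mito_rhs(y, parms))

  if (settings$method == "adaptive_rk") {
    times <- seq(settings$t_start, settings$t_end, length.out = settings$n_out)
    sol <- deSolve::ode(y = y0, times = times, func = func, parms = p,
                        method = deSolve::rkMethod("rk45dp7"),
                        rtol = settings$rtol, atol = settings$atol,
                        maxsteps = 1e6)
  } else {
    times <- seq(settings$t_start, settings$t_end, by = settings$dt)
    if (times[length(times)] < settings$t_end) {
      times <- c(times, settings$t_end)
    }
    sol <- deSolve::ode(y = y0, times = times, func = func, parms = p,
                        method = if (settings$method == "fixed_rk4") "rk4" else "euler")
  }
  sol <- unname(as.matrix(sol))
  times <- sol[, 1L]
  states <- sol[, -1L, drop = FALSE]

  if (anyNA(states) || any(!is.finite(states))) {
    bad <- which(apply(states, 1L, function(r) any(!is.finite(r))))[1L]
    last_ok <- if (bad > 1L) times[bad - 1L] else settings$t_start
    stop("integration of scenario '", scenario$cell_line, " ",
         scenario$condition, "' diverged (non-finite state); last valid time ",
         format(last_ok))
  }
  if (any(abs(states) > settings$blowup_cap)) {
    bad <- which(apply(abs(states), 1L, max) > settings$blowup_cap)[1L]
    last_ok <- if (bad > 1L) times[bad - 1L] else settings$t_start
    stop("integration of scenario '", scenario$cell_line, " ",
         scenario$condition, "' exceeded the blow-up cap ",
         format(settings$blowup_cap), "; last valid time ", format(last_ok))
  }

  diagnostics <- list(n_clipped = 0L, worst_excursion = 0)
  neg <- states < 0
  if (any(neg)) {
    worst <- min(states[neg])
    if (settings$negativity_policy == "error" && -worst > settings$clip_tol) {
      stop("scenario '", scenario$cell_line, " ", scenario$condition,
           "': negative state excursion ", format(worst),
           " under negativity_policy = 'error'")
    }
    if (-worst > settings$clip_tol) {
      warning("scenario '", scenario$cell_line, " ", scenario$condition,
              "': clipped ", sum(neg), " negative state value(s); worst ",
              format(worst))
    }
    diagnostics$n_clipped <- sum(neg)
    diagnostics$worst_excursion <- worst
    states[neg] <- 0
  }
  .new_trajectory(times, states, scenario, settings, diagnostics)
}

#' Load the phenotype parameter presets
#'
#' Reads the per-phenotype, per-condition parameter table (the packaged copy
#' of the panel's measured ultrastructure, membrane potential and OPA1/DRP1
#' levels). The CSV schema is exactly the columns
#' `cell_line, condition, c_w, c_n, c_jw, m_p, opa1, drp1` with `condition`
#' spelled `"+S"` or `"SS"`.
#'
#' The packaged table stores the OVCAR3 serum-starved row as printed in its
#' source, which carries only five numeric values for six parameter columns:
#' the membrane potential cell is empty (see the methods vignette for why
#' `m_p` is the field treated as missing). A scenario cannot be built from an
#' incomplete row; either supply the value yourself or set
#' `fill_missing = TRUE` to apply the documented fill rule, which reuses the
#' same cell line's `+S` value and records the substitution in the
#' `"filled"` attribute.
#'
#' @param path CSV file path; defaults to the packaged preset table.
#' @param fill_missing Apply the documented fill rule to incomplete rows.
#' @return A data frame of validated presets, with attribute `"filled"`
#'   describing any filled cells (NULL when none).
#' @export
#' @examples
#' presets <- load_presets(fill_missing = TRUE)
#' subset(presets, cell_line == "A4" & condition == "+S")
load_presets <- function(path = mito_presets_path(), fill_missing = FALSE) {
  if (!file.exists(path)) stop("preset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  schema <- c("cell_line", "condition", "c_w", "c_n", "c_jw", "m_p",
              "opa1", "drp1")
  if (!identical(sort(names(df)), sort(schema))) {
    missing <- setdiff(schema, names(df))
    extra <- setdiff(names(df), schema)
    stop("preset table schema error;",
         if (length(missing)) paste0(" missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0(" unexpected column(s): ",
                                   paste(extra, collapse = ", ")))
  }
  df <- df[, schema]
  if (nrow(df) == 0) stop("preset table schema error: no data rows")
  if (!all(df$condition %in% .mito_conditions)) {
    bad <- which(!df$condition %in% .mito_conditions)
    stop("preset table: condition must be '+S' or 'SS'; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  num_cols <- schema[-(1:2)]
  for (cl in num_cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      v[trimws(v) == ""] <- NA
      suppressWarnings(vn <- as.numeric(v))
      if (any(!is.na(v) & is.na(vn))) {
        stop("preset table: non-numeric values in column '", cl,
             "', row(s): ", paste(which(!is.na(v) & is.na(vn)), collapse = ", "))
      }
      df[[cl]] <- vn
    }
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    if (length(bad)) {
      stop("preset table: negative values in column '", cl, "', row(s): ",
           paste(bad, collapse = ", "))
    }
  }
  dup <- duplicated(df[, c("cell_line", "condition")])
  if (any(dup)) {
    stop("preset table: duplicated (cell_line, condition) row(s): ",
         paste(which(dup), collapse = ", "))
  }

  filled <- NULL
  if (fill_missing) {
    for (i in seq_len(nrow(df))) {
      nas <- num_cols[is.na(unlist(df[i, num_cols]))]
      for (cl in nas) {
        src <- df$cell_line == df$cell_line[i] & df$condition == "+S"
        if (!any(src) || is.na(df[[cl]][src][1])) {
          stop("cannot fill missing '", cl, "' for ", df$cell_line[i], " ",
               df$condition[i], ": no complete +S row for this cell line")
        }
        val <- df[[cl]][src][1]
        df[[cl]][i] <- val
        filled <- rbind(filled, data.frame(
          cell_line = df$cell_line[i], condition = df$condition[i],
          field = cl, value = val, stringsAsFactors = FALSE))
      }
    }
    if (!is.null(filled)) {
      message("load_presets: filled ", nrow(filled),
              " missing cell(s) from the matching +S row (",
              paste(sprintf("%s %s %s=%g", filled$cell_line, filled$condition,
                            filled$field, filled$value), collapse = "; "), ")")
    }
  }
  attr(df, "filled") <- filled
  df
}

#' @describeIn load_presets Path to the packaged preset table.
#' @export
mito_presets_path <- function() {
  system.file("extdata", "table1_presets.csv", package = "mitodyn",
              mustWork = TRUE)
}

#' Build a scenario from one preset row
#'
#' Attaches the free kinetic constants to one row of the preset table. The
#' stress level is set by condition: `stress_plus_s` (default 0, the
#' unstressed limit where both exponential factors equal 1) for `+S` and
#' `stress_ss` (default 3, the package's serum-starvation calibration; see
#' the methods vignette) for `SS`, unless `constants$stress` is meant to be
#' used verbatim (`override_stress = TRUE`).
#'
#' @param preset One-row data frame from [load_presets()].
#' @param constants Base [dynamics_constants()]; its `stress` field is
#'   replaced according to the condition unless `override_stress = TRUE`.
#' @param stress_plus_s,stress_ss Per-condition stress defaults.
#' @param override_stress Use `constants$stress` as-is for either condition.
#' @return A [scenario_params()] object.
#' @export
scenario_from_preset <- function(preset, constants = dynamics_constants(),
                                 stress_plus_s = 0, stress_ss = 3,
                                 override_stress = FALSE) {
  stopifnot(is.data.frame(preset), nrow(preset) == 1)
  vals <- unlist(preset[, c("c_w", "c_n", "c_jw", "m_p", "opa1", "drp1")])
  if (anyNA(vals)) {
    stop("preset row '", preset$cell_line, " ", preset$condition,
         "' is incomplete (missing: ",
         paste(names(vals)[is.na(vals)], collapse = ", "),
         "); supply the value or use load_presets(fill_missing = TRUE)")
  }
  if (!override_stress) {
    constants$stress <- if (preset$condition == "SS") stress_ss else stress_plus_s
  }
  scenario_params(
    cell_line = preset$cell_line, condition = preset$condition,
    structural = structural_params(preset$c_w, preset$c_n, preset$c_jw,
                                   preset$m_p),
    opa1 = preset$opa1, drp1 = preset$drp1, constants = constants,
    allow_zero_stress = TRUE)
}

#' Integrate the full phenotype-by-condition panel
#'
#' Runs [integrate_scenario()] for every requested (cell line, condition)
#' pair of the preset table — by default all rows, i.e. the five HGSC
#' phenotypes under both serum conditions. Deterministic given settings.
#'
#' @param presets Preset data frame from [load_presets()].
#' @param settings A [solver_settings()] object, shared by all scenarios.
#' @param constants Base [dynamics_constants()] passed to
#'   [scenario_from_preset()].
#' @param stress_plus_s,stress_ss Per-condition stress defaults.
#' @param initial Shared initial [system_state()].
#' @param cell_lines,conditions Optional subsets; requesting a pair absent
#'   from `presets` is an error naming the pair.
#' @return A named list of `mito_trajectory` objects (class `mito_panel`),
#'   keyed `"<cell_line> <condition>"`.
#' @export
#' @examples
#' panel <- run_panel(load_presets(fill_missing = TRUE),
#'                    solver_settings(t_end = 2, n_out = 51))
#' names(panel)
run_panel <- function(presets, settings = solver_settings(),
                      constants = dynamics_constants(),
                      stress_plus_s = 0, stress_ss = 3,
                      initial = default_initial_state(),
                      cell_lines = NULL, conditions = NULL) {
  if (is.null(cell_lines)) cell_lines <- unique(presets$cell_line)
  if (is.null(conditions)) conditions <- unique(presets$condition)
  wanted <- expand.grid(cell_line = cell_lines, condition = conditions,
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(wanted))
  keys <- character(nrow(wanted))
  for (i in seq_len(nrow(wanted))) {
    row <- presets[presets$cell_line == wanted$cell_line[i] &
                     presets$condition == wanted$condition[i], , drop = FALSE]
    if (nrow(row) == 0) {
      stop("no preset row for (", wanted$cell_line[i], ", ",
           wanted$condition[i], ")")
    }
    sc <- scenario_from_preset(row, constants = constants,
                               stress_plus_s = stress_plus_s,
                               stress_ss = stress_ss)
    out[[i]] <- integrate_scenario(sc, initial = initial, settings = settings)
    keys[i] <- paste(wanted$cell_line[i], wanted$condition[i])
  }
  names(out) <- keys
  structure(out, class = "mito_panel")
}

#' @export
print.mito_panel <- function(x, ...) {
  cat("<mito_panel> ", length(x), " trajectories: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
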