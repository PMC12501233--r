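#' Mitochondrial ultrastructure parameters
#'
#' Bundles the four normalized ultrastructural quantities that drive the ATP
#' production factor \eqn{\theta}: cristae width, cristae count per unit
#' mitochondrial length, crista junction width, and membrane potential.
#' All values are dimensionless, measured relative to the largest value
#' observed across the phenotype panel.
#'
#' @param c_w Cristae width (normalized, >= 0).
#' @param c_n Cristae count per unit mitochondrial length (normalized, >= 0).
#' @param c_jw Crista junction width (normalized, >= 0).
#' @param m_p Mitochondrial membrane potential (normalized, >= 0); enters
#'   \eqn{\theta} through \eqn{e^{m_p}}.
#'
#' @return An object of class `structural_params`.
#' @seealso [atp_production_factor()]
#' @export
#' @examples
#' structural_params(c_w = 1, c_n = 0.28, c_jw = 0.62, m_p = 0.99)
structural_params <- function(c_w, c_n, c_jw, m_p) {
  vals <- c(c_w = c_w, c_n = c_n, c_jw = c_jw, m_p = m_p)
  if (!all(is.finite(vals))) {
    stop("structural parameters must be finite numbers, got: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("structural parameters must be >= 0, offending: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  if (c_w + c_jw <= 0) {
    stop("c_w + c_jw must be > 0 (denominator of the ATP production factor)")
  }
  structure(as.list(vals), class = "structural_params")
}

#' Free rate constants and efficiency factors of the dynamics model
#'
#' The kinetic constants the phenotype panel does not measure: base fusion and
#' fission rates, mitophagy rates of the two unfused classes, the
#' healthy-over-deviant and fused-over-unfused ATP efficiency factors, the
#' constant ATP consumption, the scalar stress level, and the biogenesis mode.
#'
#' Defaults follow the package's documented calibration (see the methods
#' vignette): smallest simple efficiency factors strictly greater than 1
#' (`alpha = epsilon = 2`), deviant mitochondria cleared faster than healthy
#' ones (`M_D > M_H`), unit base fusion/fission rates, and the constant
#' consumption `mu = 3` used by the model's initial-condition statement.
#'
#' @param F_0 Base fusion rate (per time per ATP unit, >= 0).
#' @param K_0 Base fission rate (per time per ATP unit, >= 0).
#' @param M_H Mitophagy rate of healthy unfused mitochondria (per time, >= 0).
#' @param M_D Mitophagy rate of deviant unfused mitochondria (per time, >= 0).
#' @param alpha Healthy-over-deviant ATP efficiency factor (>= 1).
#' @param epsilon Fused-over-unfused ATP efficiency factor (>= 1).
#' @param mu Constant ATP consumption (ATP units per time, >= 0).
#' @param stress Scalar stress level (>= 0); serum starvation raises fusion by
#'   \eqn{e^{stress}} and lowers fission by \eqn{e^{-stress}}.
#' @param biogenesis_mode `"balance"` (biogenesis recomputed at every
#'   evaluation so that it exactly offsets total mitophagy) or `"constant"`
#'   (fixed rate `B_const`).
#' @param B_const Biogenesis rate used only in `"constant"` mode (>= 0).
#'
#' @return An object of class `dynamics_constants`.
#' @export
#' @examples
#' dynamics_constants()                    # package defaults, unstressed
#' dynamics_constants(stress = 3)          # serum-starvation default stress
dynamics_constants <- function(F_0 = 1, K_0 = 1, M_H = 0.1, M_D = 0.5,
                               alpha = 2, epsilon = 2, mu = 3, stress = 0,
                               biogenesis_mode = c("balance", "constant"),
                               B_const = 0) {
  biogenesis_mode <- match.arg(biogenesis_mode)
  nn <- c(F_0 = F_0, K_0 = K_0, M_H = M_H, M_D = M_D, mu = mu,
          B_const = B_const, stress = stress)
  if (!all(is.finite(c(nn, alpha, epsilon)))) {
    stop("dynamics constants must be finite numbers")
  }
  if (any(nn < 0)) {
    stop("dynamics constants must be >= 0, offending: ",
         paste(names(nn)[nn < 0], collapse = ", "))
  }
  if (alpha < 1) stop("alpha must be >= 1 (healthy mitochondria are the more efficient class)")
  if (epsilon < 1) stop("epsilon must be >= 1 (fused mitochondria are the more efficient class)")
  structure(list(F_0 = F_0, K_0 = K_0, M_H = M_H, M_D = M_D, alpha = alpha,
                 epsilon = epsilon, mu = mu, stress = stress,
                 biogenesis_mode = biogenesis_mode, B_const = B_const),
            class = "dynamics_constants")
}

.mito_cell_lines <- c("OVCAR3", "CAOV3", "OVCA420", "A4", "OVMZ6")
.mito_conditions <- c("+S", "SS")

#' One phenotype-by-condition scenario of the dynamics model
#'
#' Couples the measured quantities of one cell line under one culture
#' condition (ultrastructure, OPA1, DRP1) with the free kinetic constants.
#' Everything the ODE right-hand side needs lives here.
#'
#' @param cell_line One of `"OVCAR3"`, `"CAOV3"`, `"OVCA420"`, `"A4"`,
#'   `"OVMZ6"` (the epithelial-to-mesenchymal HGSC phenotype gradient).
#' @param condition `"+S"` (serum-fed) or `"SS"` (serum-starved).
#' @param structural A [structural_params()] object.
#' @param opa1 Normalized OPA1 (fusion promoter) level, >= 0.
#' @param drp1 Normalized DRP1 (fission promoter) level, >= 0.
#' @param constants A [dynamics_constants()] object. A serum-starved scenario
#'   with `stress = 0` triggers a warning unless `allow_zero_stress = TRUE`,
#'   since stress is what distinguishes the SS dynamics.
#' @param allow_zero_stress Set `TRUE` to silence the SS zero-stress warning
#'   (used e.g. by stress-continuity sweeps).
#'
#' @return An object of class `scenario_params`.
#' @export
#' @examples
#' sc <- scenario_params("OVCAR3", "+S",
#'   structural_params(1, 0.28, 0.62, 0.99),
#'   opa1 = 0.02, drp1 = 0.31, constants = dynamics_constants())
scenario_params <- function(cell_line, condition, structural, opa1, drp1,
                            constants = dynamics_constants(),
                            allow_zero_stress = FALSE) {
  cell_line <- match.arg(cell_line, .mito_cell_lines)
  condition <- match.arg(condition, .mito_conditions)
  stopifnot(inherits(structural, "structural_params"),
            inherits(constants, "dynamics_constants"))
  if (!is.finite(opa1) || opa1 < 0) stop("opa1 must be a finite number >= 0")
  if (!is.finite(drp1) || drp1 < 0) stop("drp1 must be a finite number >= 0")
  if (condition == "SS" && constants$stress <= 0 && !allow_zero_stress) {
    warning("serum-starved scenario '", cell_line,
            " SS' has stress = 0; set allow_zero_stress = TRUE if intended")
  }
  structure(list(cell_line = cell_line, condition = condition,
                 structural = structural, opa1 = opa1, drp1 = drp1,
                 constants = constants),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("<scenario %s %s>  theta = %.4f  F = %.4f  K = %.4f  stress = %g\n",
              x$cell_line, x$condition,
              atp_production_factor(x$structural),
              fusion_rate(x$constants$F_0, x$opa1),
              fission_rate(x$constants$K_0, x$drp1),
              x$constants$stress))
  invisible(x)
}

#' State of the dynamical system at one time point
#'
#' The five dynamical variables: counts of the four mitochondrial classes
#' (healthy/deviant crossed with unfused/fused) and the ATP concentration.
#'
#' @param n_hu,n_du,n_hf,n_df Counts of healthy-unfused, deviant-unfused,
#'   healthy-fused and deviant-fused mitochondria (>= 0).
#' @param atp ATP concentration in model units (>= 0 at construction; the
#'   integrator's handling of numerical excursions is a solver policy, see
#'   [solver_settings()]).
#'
#' @return An object of class `system_state`, a named numeric vector.
#' @export
#' @examples
#' default_initial_state()   # the model's reference initial condition
system_state <- function(n_hu, n_du, n_hf, n_df, atp) {
  y <- c(n_hu = n_hu, n_du = n_du, n_hf = n_hf, n_df = n_df, atp = atp)
  if (!all(is.finite(y))) stop("system state components must be finite")
  if (any(y < 0)) {
    stop("system state components must be >= 0, offending: ",
         paste(names(y)[y < 0], collapse = ", "))
  }
  structure(y, class = "system_state")
}

#' @describeIn system_state The model's reference initial condition: one
#'   mitochondrion in each class and no ATP.
#' @export
default_initial_state <- function() {
  system_state(n_hu = 1, n_du = 1, n_hf = 1, n_df = 1, atp = 0)
}

#' ATP production factor theta
#'
#' Rate factor of mitochondrial ATP production as a function of cristae
#' ultrastructure and membrane potential:
#' \deqn{\theta = \frac{c_n + e^{m_p}}{c_w + c_{jw}}}
#' More cristae and higher membrane potential increase production; broader
#' cristae and broader crista junctions (more proton leakage) decrease it.
#'
#' @param structural A [structural_params()] object.
#' @return Non-negative scalar \eqn{\theta}, strictly increasing in `c_n` and
#'   `m_p`, strictly decreasing in `c_w` and `c_jw`.
#' @export
#' @examples
#' atp_production_factor(structural_params(1, 0, 0, 0))        # = 1
#' atp_production_factor(structural_params(1, 0.28, 0.62, 0.99))
atp_production_factor <- function(structural) {
  stopifnot(inherits(structural, "structural_params"))
  denom <- structural$c_w + structural$c_jw
  if (denom <= 0) {
    stop("degenerate structural parameters: c_w + c_jw = ", denom,
         " (zero denominator in the ATP production factor)")
  }
  (structural$c_n + exp(structural$m_p)) / denom
}

#' Fusion and fission rates
#'
#' The effective fusion and fission rates scale base rates by the measured
#' levels of their promoter proteins: \eqn{F = F_0 \cdot [OPA1]} and
#' \eqn{K = K_0 \cdot [DRP1]}.
#'
#' @param F_0,K_0 Base rates (>= 0).
#' @param opa1,drp1 Normalized promoter-protein levels (>= 0).
#' @return Non-negative scalar rate.
#' @export
#' @examples
#' fusion_rate(2, 0.93)   # 1.86
#' fission_rate(1, 0.31)  # 0.31
fusion_rate <- function(F_0, opa1) {
  if (!is.finite(F_0) || F_0 < 0) stop("F_0 must be a finite number >= 0")
  if (!is.finite(opa1) || opa1 < 0) stop("opa1 must be a finite number >= 0")
  F_0 * opa1
}

#' @rdname fusion_rate
#' @export
fission_rate <- function(K_0, drp1) {
  if (!is.finite(K_0) || K_0 < 0) stop("K_0 must be a finite number >= 0")
  if (!is.finite(drp1) || drp1 < 0) stop("drp1 must be a finite number >= 0")
  K_0 * drp1
}

#' Biogenesis rate
#'
#' In `"balance"` mode biogenesis exactly offsets total mitophagy at every
#' instant, which conserves the total mitochondrial number:
#' \deqn{B (N_{HU}+N_{HF}+N_{DU}+N_{DF}) = M_H N_{HU} + M_D N_{DU}}
#' so \eqn{B = (M_H N_{HU} + M_D N_{DU}) / N_{tot}}, defined as 0 when the
#' total is 0. In `"constant"` mode `B_const` is returned unchanged.
#'
#' @param state A [system_state()] (or named numeric vector with the same
#'   components).
#' @param constants A [dynamics_constants()] object.
#' @return Non-negative scalar B.
#' @export
#' @examples
#' biogenesis_rate(default_initial_state(), dynamics_constants())  # 0.15
biogenesis_rate <- function(state, constants) {
  stopifnot(inherits(constants, "dynamics_constants"))
  y <- unclass(state)
  if (constants$biogenesis_mode == "constant") return(constants$B_const)
  total <- y[["n_hu"]] + y[["n_du"]] + y[["n_hf"]] + y[["n_df"]]
  if (total <= 0) return(0)
  (constants$M_H * y[["n_hu"]] + constants$M_D * y[["n_du"]]) / total
}

# Fast scalar right-hand side shared by state_derivative() and the
# integrator. `p` carries the precomputed theta, F, K and constants; `y` is
# the bare numeric state (n_hu, n_du, n_hf, n_df, atp). When `p$atp_floor`
# is TRUE the ATP entering the exchange terms is clamped at 0 and the ATP
# derivative cannot push ATP below 0 (mu is otherwise a constant drain the
# model does not switch off).
.mito_rhs <- function(y, p) {
  nhu <- y[1L]; ndu <- y[2L]; nhf <- y[3L]; ndf <- y[4L]; atp <- y[5L]
  atp_eff <- if (p$atp_floor && atp < 0) 0 else atp
  B <- if (p$balance) {
    total <- nhu + ndu + nhf + ndf
    if (total <= 0) 0 else (p$M_H * nhu + p$M_D * ndu) / total
  } else {
    p$B_const
  }
  fa <- p$Frate * atp_eff * p$es    # F [ATP] e^{stress}
  ka <- p$Krate * atp_eff * p$ens   # K [ATP] e^{-stress}
  dhu <- (B - p$M_H - fa) * nhu + ka * nhf
  ddu <- (B - p$M_D - fa) * ndu + ka * ndf
  dhf <- (B - ka) * nhf + fa * nhu
  ddf <- (B - ka) * ndf + fa * ndu
  datp <- p$theta * (p$epsilon * (p$alpha * nhf + ndf) + (p$alpha * nhu + ndu)) -
    p$mu - ka * (nhf + ndf) - fa * ndu - fa * nhu
  if (p$atp_floor && atp <= 0 && datp < 0) datp <- 0
  c(dhu, ddu, dhf, ddf, datp)
}

# Precompute the parameter list .mito_rhs() consumes.
.rhs_params <- function(scenario, atp_floor = FALSE) {
  cs <- scenario$constants
  theta <- tryCatch(
    atp_production_factor(scenario$structural),
    error = function(e) {
      stop("scenario '", scenario$cell_line, " ", scenario$condition, "': ",
           conditionMessage(e), call. = FALSE)
    })
  list(theta = theta,
       Frate = fusion_rate(cs$F_0, scenario$opa1),
       Krate = fission_rate(cs$K_0, scenario$drp1),
       M_H = cs$M_H, M_D = cs$M_D,
       alpha = cs$alpha, epsilon = cs$epsilon, mu = cs$mu,
       es = exp(cs$stress), ens = exp(-cs$stress),
       balance = identical(cs$biogenesis_mode, "balance"),
       B_const = cs$B_const,
       atp_floor = isTRUE(atp_floor))
}

#' Right-hand side of the coupled ODE system
#'
#' Evaluates the instantaneous derivative of the five-variable system.
#' Fusion converts unfused to fused mitochondria at rate
#' \eqn{F [ATP] e^{stress}} and fission converts back at
#' \eqn{K [ATP] e^{-stress}}; only unfused classes are removed by mitophagy
#' (\eqn{M_H}, \eqn{M_D}); biogenesis feeds every class at rate \eqn{B}
#' proportionally to its size. ATP is produced at rate \eqn{\theta} weighted
#' by the efficiency factors \eqn{\alpha} (healthy over deviant) and
#' \eqn{\epsilon} (fused over unfused), drained at the constant rate
#' \eqn{\mu}, and consumed by both fusion and fission events:
#' \deqn{dN_{HU}/dt = (B - M_H - F[ATP]e^{s}) N_{HU} + K[ATP]e^{-s} N_{HF}}
#' \deqn{dN_{DU}/dt = (B - M_D - F[ATP]e^{s}) N_{DU} + K[ATP]e^{-s} N_{DF}}
#' \deqn{dN_{HF}/dt = (B - K[ATP]e^{-s}) N_{HF} + F[ATP]e^{s} N_{HU}}
#' \deqn{dN_{DF}/dt = (B - K[ATP]e^{-s}) N_{DF} + F[ATP]e^{s} N_{DU}}
#' \deqn{d[ATP]/dt = \theta[\epsilon(\alpha N_{HF} + N_{DF}) +
#'   (\alpha N_{HU} + N_{DU})] - \mu - K[ATP](N_{HF}+N_{DF})e^{-s} -
#'   F[ATP] N_{DU} e^{s} - F[ATP] N_{HU} e^{s}}
#'
#' @param state A [system_state()] or named numeric vector of the five
#'   components.
#' @param scenario A [scenario_params()] object.
#' @return Named numeric vector `(n_hu, n_du, n_hf, n_df, atp)` of
#'   derivatives.
#' @export
#' @examples
#' sc <- scenario_params("OVCAR3", "+S", structural_params(1, 0.28, 0.62, 0.99),
#'                       opa1 = 0.02, drp1 = 0.31)
#' state_derivative(default_initial_state(), sc)
state_derivative <- function(state, scenario) {
  stopifnot(inherits(scenario, "scenario_params"))
  y <- unclass(state)
  if (!all(c("n_hu", "n_du", "n_hf", "n_df", "atp") %in% names(y))) {
    stop("state must carry components n_hu, n_du, n_hf, n_df, atp")
  }
  y <- as.numeric(y[c("n_hu", "n_du", "n_hf", "n_df", "atp")])
  d <- .mito_rhs(y, .rhs_params(scenario))
  names(d) <- c("n_hu", "n_du", "n_hf", "n_df", "atp")
  d
}
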