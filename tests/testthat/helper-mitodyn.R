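# Shared fixtures and the independent fixed-step Euler oracle used to
# cross-check the package's integrators. The oracle is written directly from
# the model equations (scalar arithmetic, no package/deSolve code) so the
# two routes to a solution stay independent.

# Forward-Euler solve of the five coupled ODEs from one preset row.
# `cs` is a plain list of the free constants.
euler_oracle <- function(row, cs, stress, t_end, dt,
                         y0 = c(1, 1, 1, 1, 0)) {
  theta <- (row$c_n + exp(row$m_p)) / (row$c_w + row$c_jw)
  Fr <- cs$F_0 * row$opa1
  Kr <- cs$K_0 * row$drp1
  es <- exp(stress); ens <- exp(-stress)
  MH <- cs$M_H; MD <- cs$M_D
  al <- cs$alpha; ep <- cs$epsilon; mu <- cs$mu
  nhu <- y0[1]; ndu <- y0[2]; nhf <- y0[3]; ndf <- y0[4]; atp <- y0[5]
  nsteps <- round(t_end / dt)
  for (i in seq_len(nsteps)) {
    total <- nhu + ndu + nhf + ndf
    B <- if (total > 0) (MH * nhu + MD * ndu) / total else 0
    a <- if (atp < 0) 0 else atp
    fa <- Fr * a * es
    ka <- Kr * a * ens
    d1 <- (B - MH - fa) * nhu + ka * nhf
    d2 <- (B - MD - fa) * ndu + ka * ndf
    d3 <- (B - ka) * nhf + fa * nhu
    d4 <- (B - ka) * ndf + fa * ndu
    d5 <- theta * (ep * (al * nhf + ndf) + (al * nhu + ndu)) - mu -
      ka * (nhf + ndf) - fa * ndu - fa * nhu
    if (atp <= 0 && d5 < 0) d5 <- 0
    nhu <- nhu + dt * d1
    ndu <- ndu + dt * d2
    nhf <- nhf + dt * d3
    ndf <- ndf + dt * d4
    atp <- atp + dt * d5
  }
  c(n_hu = nhu, n_du = ndu, n_hf = nhf, n_df = ndf, atp = atp)
}

default_constants_list <- function() {
  list(F_0 = 1, K_0 = 1, M_H = 0.1, M_D = 0.5, alpha = 2, epsilon = 2, mu = 3)
}

# Normwise relative error between two state vectors.
rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

# Scenario engineered so that theta = 1 ((0 + e^0) / (1 + 0)).
theta_one_scenario <- function(constants) {
  scenario_params("OVCAR3", "+S",
                  structural_params(c_w = 1, c_n = 0, c_jw = 0, m_p = 0),
                  opa1 = 1, drp1 = 1, constants = constants)
}

# Single-point trajectory with an arbitrary state, for readout functions.
point_trajectory <- function(n_hu, n_du, n_hf, n_df, atp,
                             cell_line = "A4", condition = "+S") {
  sc <- scenario_params(cell_line, condition,
                        structural_params(1, 1, 1, 1), opa1 = 1, drp1 = 1)
  integrate_scenario(sc,
                     initial = system_state(n_hu, n_du, n_hf, n_df, atp),
                     settings = solver_settings(t_start = 0, t_end = 0))
}

presets_filled <- function() {
  suppressMessages(load_presets(fill_missing = TRUE))
}

# Minimal hand-built LFQ row.
lfq_row <- function(id = "P1", ss = c(400, 380, 420), s = c(100, 95, 105),
                    peptides = 3, coverage = 30) {
  ss <- c(ss, rep(NA_real_, 3 - length(ss)))
  s <- c(s, rep(NA_real_, 3 - length(s)))
  data.frame(protein_id = id, ss_1 = ss[1], ss_2 = ss[2], ss_3 = ss[3],
             s_1 = s[1], s_2 = s[2], s_3 = s[3],
             peptides = peptides, coverage = coverage,
             stringsAsFactors = FALSE)
}
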