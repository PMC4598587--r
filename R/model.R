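#' Repressible promoter activity
#'
#' Transcription rate of the prepro alpha-factor promoter under repressor
#' load: `gamma / (1 + (Z / beta_c)^hill_rep)`. Strictly decreasing in `Z`,
#' equal to `gamma` at `Z = 0`, tending to 0 as `Z` grows.
#'
#' @param Z Repressor concentration, mmol/ml (>= 0).
#' @param gamma Maximal transcription rate, mmol/(ml*s).
#' @param beta_c Repression constant, mmol/ml (> 0).
#' @param hill_rep Hill coefficient of repression.
#' @return Transcription rate, mmol/(ml*s). Vectorized over `Z`.
#' @export
repressible_promoter_activity <- function(Z, gamma, beta_c, hill_rep = 2) {
  if (any(Z < 0)) stop("Z must be >= 0")
  if (beta_c <= 0) stop("beta_c must be > 0")
  gamma / (1 + (Z / beta_c)^hill_rep)
}

#' Consortium right-hand side (reference R implementation)
#'
#' Time derivative of the 13-component consortium state. This is the
#' documented reference implementation; the integrator uses an identical
#' compiled version (their agreement is part of the test suite).
#'
#' Model structure: sender cells transcribe prepro alpha-factor mRNA under
#' input Hill induction, translate and secrete; NOT cells sense their cognate
#' medium pheromone through a saturable pathway stage `F`, produce repressor
#' `Z` at rate `k34 * F`, and transcribe their own prepro alpha-factor from a
#' repressible promoter; the medium pools receive secretion from cell 2 +
#' cell 3 (X) and cell 1 + cell 4 (Y), scaled by cell density, and are
#' cleared at `k_alpha_deg`; GFP is co-expressed with `phi_y` in cell 4.
#'
#' @param state Named or positional numeric vector of length 13 in
#'   [state_names()] order, all components >= 0.
#' @param t Time, s (the system is autonomous within an input segment; `t`
#'   is accepted for interface completeness).
#' @param params A `circuit_params` object.
#' @param inputs Numeric pair `c(R, S)` of input concentrations, ug/ml.
#' @param clamp_medium If `TRUE`, medium pools are held fixed and NOT cells
#'   see zero ligand (used by pre-equilibration).
#' @return Named derivative vector of length 13.
#' @export
circuit_rhs <- function(state, t = 0, params = default_params(),
                        inputs = c(0, 0), clamp_medium = FALSE) {
  if (length(state) != 13L) stop("state must have 13 components")
  if (any(!is.finite(state))) stop("non-finite state component")
  if (any(state < 0)) stop("negative state component")
  if (any(inputs < 0)) stop("inputs must be >= 0")
  pv <- expand_params(params)
  hill <- function(u, K, n) if (u <= 0) 0 else u^n / (K^n + u^n)
  s <- as.numeric(state)
  names(s) <- state_names()
  R <- inputs[[1]]; S <- inputs[[2]]
  pr <- function(cell, f) pv[[paste0(f, "_", cell)]]
  d <- numeric(13)
  # senders
  for (cc in 1:2) {
    inp <- if (cc == 1) R else S
    i <- 2 * (cc - 1)
    d[i + 1] <- pr(cc, "k_tx") * hill(inp, pr(cc, "K_u"), pr(cc, "hill_in")) +
      pr(cc, "k_tx0") - pr(cc, "d_m") * s[i + 1]
    d[i + 2] <- pr(cc, "k_tl") * s[i + 1] -
      (pr(cc, "k_sec") + pr(cc, "d_p")) * s[i + 2]
  }
  # NOT cells: cell 3 senses Y_med, cell 4 senses X_med
  for (cc in 3:4) {
    i <- 4 + 3 * (cc - 3)
    lig <- if (clamp_medium) 0 else if (cc == 3) s["Y_med"] else s["X_med"]
    u <- lig / (pr(cc, "K_L") + lig)
    d[i + 1] <- pr(cc, "k_act") * u * (pr(cc, "F_tot") - s[i + 1]) -
      pr(cc, "k_deact") * s[i + 1]
    d[i + 2] <- pr(cc, "k34") * s[i + 1] - pr(cc, "d_Z") * s[i + 2]
    d[i + 3] <- repressible_promoter_activity(
      s[i + 2], pr(cc, "gamma"), pr(cc, "beta_c"), pr(cc, "hill_rep")) -
      (pr(cc, "k_sec") + pr(cc, "d_p")) * s[i + 3]
  }
  # medium
  if (!clamp_medium) {
    d[11] <- pv[["sigma_2"]] * s["A2"] + pv[["sigma_3"]] * s["phi_x"] -
      pv[["k_deg_x"]] * s["X_med"]
    d[12] <- pv[["sigma_1"]] * s["A1"] + pv[["sigma_4"]] * s["phi_y"] -
      pv[["k_deg_y"]] * s["Y_med"]
  }
  # GFP
  d[13] <- pv[["k_gfp"]] * repressible_promoter_activity(
    s["Z4"], 1, pv[["beta_c_4"]], pv[["hill_rep_4"]]) -
    pv[["k_gfp_deg"]] * s["GFP"]
  if (any(!is.finite(d))) stop("non-finite derivative component")
  names(d) <- state_names()
  d
}

#' Mirror a state under the X/Y relabeling
#'
#' Applies the symmetry map of the circuit: exchanges cells 1 and 2, cells 3
#' and 4, and the two medium pheromones. For a symmetric parameter set,
#' swapping the inputs `(R, S) -> (S, R)` and mirroring the state commutes
#' with the right-hand side. GFP is not part of the core symmetry (it sits
#' only in cell 4) and is carried through unchanged.
#'
#' @param state Numeric vector of length 13 in [state_names()] order.
#' @return The mirrored state vector.
#' @export
mirror_state <- function(state) {
  if (length(state) != 13L) stop("state must have 13 components")
  s <- as.numeric(state)
  m <- s[c(3, 4, 1, 2, 8, 9, 10, 5, 6, 7, 12, 11, 13)]
  names(m) <- state_names()
  m
}
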