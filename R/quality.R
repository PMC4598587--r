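# Flip-flop quality statistics.
#
# The readout Phi(t) = phi_x - phi_y is scored over a four-interval window
# t0..t4 (canonical: 0, 180, 900, 1080, 1800 min). Activation intervals
# ([t0,t1], [t2,t3]) are scored with sign indicators (only correctly-signed
# excursions count); hold intervals ([t1,t2], [t3,t4]) are scored with the
# signed integral so wrong-sign excursions subtract. Perfect areas are the
# rectangles spanned by the global extrema m < 0 < M.

.trapz <- function(t, f) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (f[-1] + f[-n]) / 2)
}

# window of a phi series on [a, b] with interpolated endpoints
.phi_window <- function(phi, a, b) {
  t <- phi$time
  v <- phi$phi
  if (a < t[1] - 1e-9 || b > t[length(t)] + 1e-9)
    stop("phi series does not cover [", a, ", ", b, "] s")
  inside <- which(t > a & t < b)
  ts <- c(a, t[inside], b)
  vs <- c(stats::approx(t, v, xout = a)$y, v[inside],
          stats::approx(t, v, xout = b)$y)
  list(t = ts, v = vs)
}

.need_breaks <- function(phi) {
  bp <- phi$breakpoints
  if (length(bp) != 5L)
    stop("quality scoring needs exactly 5 breakpoints (4 intervals), got ",
         length(bp))
  bp
}

#' Real response areas
#'
#' Integrals of the readout over the four scoring intervals, in
#' mmol*min/ml. `R1` and `R3` carry the sign indicators (R1 integrates only
#' negative values on the first write interval, R3 only positive values on
#' the second); `R2` and `R4` are plain signed integrals over the hold
#' intervals, so wrong-sign excursions subtract. Trapezoidal quadrature on
#' the saved grid.
#'
#' @param phi A `phi_series` covering all breakpoints.
#' @return Named numeric vector `c(R1, R2, R3, R4)`, mmol*min/ml.
#' @export
real_areas <- function(phi) {
  bp <- .need_breaks(phi)
  w <- lapply(1:4, function(i) .phi_window(phi, bp[i], bp[i + 1]))
  R1 <- .trapz(w[[1]]$t, pmin(w[[1]]$v, 0)) / 60
  R2 <- .trapz(w[[2]]$t, w[[2]]$v) / 60
  R3 <- .trapz(w[[3]]$t, pmax(w[[3]]$v, 0)) / 60
  R4 <- .trapz(w[[4]]$t, w[[4]]$v) / 60
  c(R1 = R1, R2 = R2, R3 = R3, R4 = R4)
}

#' Perfect reference areas
#'
#' Signed rectangles spanned by the global extrema of the readout:
#' `P1 = m*(t1-t0)`, `P2 = m*(t2-t1)` (negative for a switching signal),
#' `P3 = M*(t3-t2)`, `P4 = M*(t4-t3)` (positive). Each ratio `Ri/Pi` is 1
#' for the ideal rectangular signal.
#'
#' @param phi A `phi_series` covering all breakpoints.
#' @return Named numeric vector `c(P1, P2, P3, P4)`, mmol*min/ml.
#' @export
perfect_areas <- function(phi) {
  bp <- .need_breaks(phi)
  dmin <- diff(bp) / 60
  c(P1 = phi$m * dmin[1], P2 = phi$m * dmin[2],
    P3 = phi$M * dmin[3], P4 = phi$M * dmin[4])
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Shape quality of the flip-flop signal
#'
#' Computes the Pareto-weighted shape quality
#' `theta_S = lambda * S_r + (1 - lambda) * S_m`, where
#' `S_r = (R1/P1 + R3/P3) / 2` measures response fidelity in the write
#' intervals and `S_m = (R2/P2 + R4/P4) / 2` measures memory persistence in
#' the hold intervals. Each area ratio and the final score are clamped to
#' \[0, 1\].
#'
#' Zero-quality rules (applied before anything else): the score is 0 if the
#' readout has no negative values in the first half of the scored window,
#' or no positive values in the second half (canonical protocol: the first
#' and last 15 h). A degenerate non-switching signal (m = 0 or M = 0) also
#' scores 0.
#'
#' @param phi A `phi_series` covering all breakpoints.
#' @param lam Pareto weight in \[0, 1\]; 1 scores only the response, 0 only
#'   the memory.
#' @return An object of class `quality_score`: list with `S_r`, `S_m`,
#'   `theta_S`, `theta_A` (`NA` until normalized within a sweep), `lambda`,
#'   `R1..R4`, `P1..P4`, `m`, `M`, and `zero_rule` (why the score was forced
#'   to 0, or `"none"`).
#' @export
theta_S <- function(phi, lam = 0.4) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("lambda must be a scalar in [0, 1]")
  bp <- .need_breaks(phi)
  mid <- (bp[1] + bp[5]) / 2
  first <- .phi_window(phi, bp[1], mid)
  second <- .phi_window(phi, mid, bp[5])

  zero_rule <- "none"
  if (min(first$v) >= 0) zero_rule <- "no_negative_first_half"
  else if (max(second$v) <= 0) zero_rule <- "no_positive_second_half"
  else if (phi$m == 0 || phi$M == 0) zero_rule <- "degenerate_amplitude"

  if (zero_rule != "none") {
    degenerate <- zero_rule == "degenerate_amplitude"
    R <- if (degenerate) c(R1 = 0, R2 = 0, R3 = 0, R4 = 0) else real_areas(phi)
    P <- if (degenerate) c(P1 = 0, P2 = 0, P3 = 0, P4 = 0) else perfect_areas(phi)
    sc <- list(S_r = 0, S_m = 0, theta_S = 0, theta_A = NA_real_,
               lambda = lam, R = R, P = P, m = phi$m, M = phi$M,
               zero_rule = zero_rule)
    class(sc) <- "quality_score"
    return(sc)
  }

  R <- real_areas(phi)
  P <- perfect_areas(phi)
  r <- .clamp01(R / P)
  S_r <- (r[["R1"]] + r[["R3"]]) / 2
  S_m <- (r[["R2"]] + r[["R4"]]) / 2
  sc <- list(S_r = S_r, S_m = S_m,
             theta_S = .clamp01(lam * S_r + (1 - lam) * S_m),
             theta_A = NA_real_, lambda = lam, R = R, P = P,
             m = phi$m, M = phi$M, zero_rule = "none")
  class(sc) <- "quality_score"
  sc
}

#' Amplitude-normalized quality
#'
#' Scales the shape quality by the signal amplitude relative to the largest
#' amplitudes found in a parameter sweep Omega:
#' `theta_A = theta_S * (m * M) / (m_T * M_T)`, where `m_T` is the most
#' negative minimum and `M_T` the largest maximum over the sweep. Within
#' its own sweep the normalizer ratio is at most 1, so
#' `theta_A <= theta_S`.
#'
#' @param score A `quality_score` from [theta_S()].
#' @param m_T Sweep-wide minimum (most negative m), mmol/ml; must be < 0.
#' @param M_T Sweep-wide maximum, mmol/ml; must be > 0.
#' @return The amplitude-normalized quality, dimensionless.
#' @export
theta_A <- function(score, m_T, M_T) {
  stopifnot(inherits(score, "quality_score"))
  if (m_T * M_T == 0) stop("m_T * M_T must be non-zero")
  if (!(m_T < 0 && M_T > 0))
    stop("a valid sweep has m_T < 0 < M_T")
  score$theta_S * (score$m * score$M) / (m_T * M_T)
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf(
    "<quality_score> theta_S = %.4f (S_r = %.4f, S_m = %.4f, lambda = %.2f)\n",
    x$theta_S, x$S_r, x$S_m, x$lambda))
  if (x$zero_rule != "none") cat("  zero-quality rule: ", x$zero_rule, "\n")
  invisible(x)
}

#' Ideal and degraded flip-flop fixtures
#'
#' Generates a synthetic readout series without running the ODE model: the
#' ideal rectangular flip-flop signal (`phi = m` up to the second write at
#' t2, `phi = M` afterwards), optionally degraded by exponential relaxation
#' toward 0 during the hold windows (rate `relax_rate`, 1/s) and/or a delay
#' `flip_delay_s` of the m-to-M transition. The discontinuity is encoded by
#' two samples 1e-6 s apart so trapezoidal quadrature resolves the jump
#' exactly.
#'
#' @param m Low level, mmol/ml (< 0).
#' @param M High level, mmol/ml (> 0).
#' @param breakpoints The five scoring breakpoints, s. Default canonical
#'   (0, 180, 900, 1080, 1800 min).
#' @param dt_s Sampling cadence, s.
#' @param relax_rate Exponential relaxation rate toward 0 in the hold
#'   windows, 1/s (0 = ideal).
#' @param flip_delay_s Delay of the low-to-high transition past t2, s.
#' @return A `phi_series`.
#' @export
ideal_signal <- function(m, M, breakpoints = canonical_breakpoints(),
                         dt_s = 60, relax_rate = 0, flip_delay_s = 0) {
  if (!(m < 0 && M > 0)) stop("need m < 0 < M")
  bp <- as.numeric(breakpoints)
  if (length(bp) != 5L || any(diff(bp) <= 0))
    stop("breakpoints must be 5 increasing values")
  if (flip_delay_s < 0 || flip_delay_s >= bp[4] - bp[3])
    stop("flip_delay_s must lie within [0, t3 - t2)")
  tflip <- bp[3] + flip_delay_s
  grid <- sort(unique(c(seq(bp[1], bp[5], by = dt_s), bp, tflip)))
  eps <- 1e-6
  grid <- sort(unique(c(grid, tflip + eps)))
  low <- function(t) {
    # m-branch: constant during write, relaxing toward 0 in hold [t1, t2]
    ifelse(t <= bp[2], m, m * exp(-relax_rate * (pmin(t, bp[3]) - bp[2])))
  }
  high <- function(t) {
    ifelse(t <= bp[4], M, M * exp(-relax_rate * (t - bp[4])))
  }
  phi <- ifelse(grid <= tflip, low(grid), high(grid))
  phi_series(grid, phi, bp)
}

#' Canonical scoring breakpoints
#'
#' @return `c(0, 180, 900, 1080, 1800) * 60` seconds.
#' @export
canonical_breakpoints <- function() c(0, 180, 900, 1080, 1800) * 60

#' Serialize a quality score to JSON
#'
#' Keys: `S_r`, `S_m`, `theta_S`, `theta_A`, `R1..R4`, `P1..P4`, `m`, `M`,
#' `lambda`.
#'
#' @param score A `quality_score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_json <- function(score, path) {
  out <- c(list(S_r = score$S_r, S_m = score$S_m, theta_S = score$theta_S,
                theta_A = score$theta_A),
           as.list(score$R), as.list(score$P),
           list(m = score$m, M = score$M, lambda = score$lambda))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
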