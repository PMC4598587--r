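# Oracles: the area examples are checked against fine-grid Riemann sums and
# closed-form integrals computed independently of the package quadrature.

riemann <- function(f, a, b, n = 2e5) {
  t <- seq(a, b, length.out = n)
  sum(f((t[-1] + t[-n]) / 2)) * (b - a) / (n - 1)
}

test_that("real areas apply the sign indicators and signed hold integrals", {
  bp <- canonical_breakpoints()
  # constant -1 through the first write window
  phi <- step_phi(c(-1, -1, 1, 1), c(0, 180, 900, 1080) * 60)
  R <- real_areas(phi)
  expect_equal(unname(R["R1"]), -180)
  # theta_1 kills positive values
  phi_pos <- step_phi(c(1, -1, 1, 1), c(0, 180, 900, 1080) * 60)
  expect_equal(unname(real_areas(phi_pos)["R1"]), 0)
  # wrong-sign excursion subtracts in a hold window: -1 on the first half
  # of [t1, t2], +0.5 on the second half
  phi_mix <- step_phi(c(-1, -1, 0.5, 1, 1), c(0, 180, 540, 900, 1080) * 60)
  R2 <- unname(real_areas(phi_mix)["R2"])
  expect_equal(R2, -180)
  f <- function(t) ifelse(t < 540 * 60, -1, 0.5)
  expect_equal(R2, riemann(f, bp[2], bp[3]) / 60, tolerance = 1e-4)
})

test_that("perfect areas are the extrema rectangles", {
  phi <- ideal_signal(-1, 1)
  expect_equal(unname(perfect_areas(phi)), c(-180, -720, 180, 720))
  # asymmetric extrema used on their own sides
  phi2 <- step_phi(c(-2, -2, 1, 1), c(0, 180, 900, 1080) * 60)
  P <- perfect_areas(phi2)
  expect_equal(unname(P["P1"]), -360)
  expect_equal(unname(P["P3"]), 180)
  # ideal signal: real equals perfect in every interval
  expect_equal(unname(real_areas(phi)), unname(perfect_areas(phi)),
               tolerance = 1e-9)
})

test_that("ideal rectangular signal scores 1 at every lambda", {
  phi <- ideal_signal(-1, 1)
  for (lam in c(0, 0.25, 0.5, 0.75, 1))
    expect_equal(theta_S(phi, lam)$theta_S, 1, tolerance = 1e-9)
  phi_a <- ideal_signal(-3e-10, 8e-10) # asymmetric amplitudes
  expect_equal(theta_S(phi_a, 0.4)$theta_S, 1, tolerance = 1e-9)
})

test_that("zero-quality rules fire before scoring", {
  grid <- seq(0, 1800 * 60, by = 60)
  all_pos <- phi_series(grid, rep(1, length(grid)), canonical_breakpoints())
  expect_equal(theta_S(all_pos, 0.4)$theta_S, 0)
  expect_equal(theta_S(all_pos, 0.4)$zero_rule, "no_negative_first_half")
  all_neg <- phi_series(grid, rep(-1, length(grid)), canonical_breakpoints())
  expect_equal(theta_S(all_neg, 0.4)$theta_S, 0)
  expect_equal(theta_S(all_neg, 0.4)$zero_rule, "no_positive_second_half")
})

test_that("memory-free fixture scores lambda exactly", {
  # ideal during the write windows, flat zero during both hold windows
  phi <- step_phi(c(-1, 0, 1, 0), c(0, 180, 900, 1080) * 60)
  sc <- theta_S(phi, 0.4)
  expect_equal(sc$S_r, 1, tolerance = 1e-9)
  expect_equal(sc$S_m, 0, tolerance = 1e-9)
  expect_equal(sc$theta_S, 0.4, tolerance = 1e-9)
})

test_that("exponential hold relaxation matches the closed-form integral", {
  # trapezoid error scales as (r*dt)^2/12: the 1-min grid meets 1e-6 for
  # the 6-h half-life; faster relaxations need the finer grid
  cases <- list(c(6, 60), c(6, 10), c(2, 10))
  for (cs in cases) {
    r <- log(2) / (cs[1] * 3600)
    phi <- ideal_signal(-1, 1, relax_rate = r, dt_s = cs[2])
    sc <- theta_S(phi, 0.4)
    delta <- 720 * 60
    ratio <- (1 - exp(-r * delta)) / (r * delta)
    expect_equal(sc$S_m, ratio, tolerance = 1e-6)
    expect_equal(sc$S_r, 1, tolerance = 1e-6)
    expect_equal(sc$theta_S, 0.4 + 0.6 * ratio, tolerance = 1e-6)
  }
  # instant relaxation destroys the memory score
  expect_lt(theta_S(ideal_signal(-1, 1, relax_rate = 1, dt_s = 1),
                    0)$theta_S, 1e-4)
})

test_that("theta_S is affine in lambda and scale invariant", {
  phi <- ideal_signal(-1, 1, relax_rate = log(2) / (6 * 3600))
  th <- vapply(c(0, 0.25, 0.5, 0.75, 1),
               function(l) theta_S(phi, l)$theta_S, numeric(1))
  expect_equal(th[3], (th[1] + th[5]) / 2, tolerance = 1e-12)
  expect_equal(diff(th), rep(diff(th)[1], 4), tolerance = 1e-12)
  expect_equal(th[1], theta_S(phi, 0)$S_m)
  expect_equal(th[5], theta_S(phi, 1)$S_r)
  # scaling phi leaves the shape score untouched, scales the amplitudes
  c0 <- 3.7e-10
  phi_s <- phi_series(phi$time, c0 * phi$phi, phi$breakpoints)
  sc <- theta_S(phi, 0.4); sc_s <- theta_S(phi_s, 0.4)
  expect_equal(sc_s$theta_S, sc$theta_S, tolerance = 1e-12)
  expect_equal(sc_s$S_r, sc$S_r, tolerance = 1e-12)
  expect_equal(sc_s$m, c0 * sc$m)
  expect_equal(sc_s$M, c0 * sc$M)
})

test_that("a sign flip in one hold window strictly lowers the memory score", {
  base <- step_phi(c(-1, -1, 1, 1), c(0, 180, 900, 1080) * 60)
  flipped <- step_phi(c(-1, -1, 1, 1, 1), c(0, 180, 540, 900, 1080) * 60)
  # flipped: phi = +1 on the second half of the first hold window
  expect_lt(theta_S(flipped, 0)$S_m, theta_S(base, 0)$S_m)
  expect_equal(theta_S(base, 0)$S_m, 1, tolerance = 1e-9)
})

test_that("theta_A normalizes amplitude within a sweep", {
  sc <- theta_S(ideal_signal(-2e-10, 1e-10), 0.4)
  # the sweep's own extreme point is the fixed point
  expect_equal(theta_A(sc, sc$m, sc$M), sc$theta_S)
  # direct evaluation at half the sweep extrema
  sc8 <- structure(list(theta_S = 0.8, m = -1e-10, M = 5e-11),
                   class = "quality_score")
  expect_equal(theta_A(sc8, -2e-10, 1e-10), 0.2)
  expect_error(theta_A(sc, 0, 1e-10), "non-zero")
  expect_error(theta_A(sc, 1e-10, 1e-10), "m_T < 0")
})

test_that("malformed inputs are rejected", {
  phi <- ideal_signal(-1, 1)
  expect_error(theta_S(phi, 1.2), "lambda")
  expect_error(theta_S(phi, -0.1), "lambda")
  expect_error(ideal_signal(1, 2), "m < 0")
  expect_error(phi_series(1:10, 1:10, c(0, 1, 2, 3, 20)), "cover")
  # scoring needs exactly 4 intervals
  sch3 <- canonical_sequence(3, 20, 3)
  long_bp <- attr(sch3, "breakpoints_s")
  long <- phi_series(seq(0, 138 * 3600, 600),
                     sin(seq(0, 138 * 3600, 600) / 1e4) * 1e-10, long_bp)
  expect_error(real_areas(long), "5 breakpoints")
})
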