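test_that("repressible promoter follows the closed form", {
  g <- 1e-12
  expect_equal(repressible_promoter_activity(0, g, 1e-11), g)
  expect_equal(repressible_promoter_activity(1e-11, g, 1e-11, 1), g / 2)
  expect_equal(repressible_promoter_activity(1e-10, g, 1e-11, 2), g / 101)
  # strictly decreasing in Z
  z <- 10^seq(-13, -9, length.out = 30)
  act <- repressible_promoter_activity(z, g, 1e-11, 2)
  expect_true(all(diff(act) < 0))
  expect_error(repressible_promoter_activity(1e-11, g, 0), "beta_c")
  expect_error(repressible_promoter_activity(-1e-12, g, 1e-11), "Z")
})

test_that("origin is absorbing when all constitutive sources are off", {
  p <- circuit_params(gamma = 0, k_tx0 = 0, k_gfp = 0)
  d <- circuit_rhs(numeric(13), 0, p, inputs = c(0, 0))
  expect_equal(unname(d), numeric(13))
})

test_that("medium clearance is the only loss with sources silenced", {
  p <- default_params()
  s <- numeric(13)
  s[12] <- 3e-11 # Y_med only
  d <- circuit_rhs(s, 0, p, inputs = c(0, 0))
  expect_equal(unname(d["Y_med"]), -p$k_alpha_deg * 3e-11)
  expect_equal(unname(d["X_med"]), 0)
})

test_that("rhs commutes with the mirror map for symmetric parameters", {
  set.seed(42)
  p <- default_params()
  for (i in 1:100) {
    s <- random_state()
    inp <- stats::runif(2, 0, 200)
    d1 <- mirror_state(circuit_rhs(s, 0, p, inputs = inp))
    d2 <- circuit_rhs(mirror_state(s), 0, p, inputs = rev(inp))
    # GFP sits only in cell 4 and is excluded from the core symmetry
    expect_equal(unname(d1[1:12]), unname(d2[1:12]), tolerance = 1e-14)
  }
})

test_that("compiled rhs and Jacobian agree with the R reference", {
  set.seed(7)
  p <- circuit_params(overrides = list(cell3 = list(gamma = 3e-12),
                                       cell4 = list(beta_c = 2e-11)))
  pv <- expand_params(p)
  for (i in 1:25) {
    s <- random_state()
    inp <- stats::runif(2, 0, 200)
    expect_equal(unname(srlatch:::circuit_rhs_cpp(s, pv, inp[1], inp[2], FALSE)),
                 unname(circuit_rhs(s, 0, p, inputs = inp)),
                 tolerance = 1e-14)
  }
  # analytic Jacobian vs central finite differences of the rhs
  s <- random_state()
  J <- srlatch:::circuit_jac_cpp(s, pv, FALSE)
  Jfd <- matrix(0, 13, 13)
  for (j in 1:13) {
    h <- max(abs(s[j]), 1e-12 * max(s)) * 1e-6
    sp <- s; sm <- s
    sp[j] <- s[j] + h; sm[j] <- max(s[j] - h, 0)
    Jfd[, j] <- (srlatch:::circuit_rhs_cpp(sp, pv, 10, 20, FALSE) -
                   srlatch:::circuit_rhs_cpp(sm, pv, 10, 20, FALSE)) /
      (sp[j] - sm[j])
  }
  scale <- max(abs(J))
  expect_lt(max(abs(J - Jfd)) / scale, 1e-5)
})

test_that("rhs rejects invalid states", {
  s <- numeric(13); s[1] <- -1e-12
  expect_error(circuit_rhs(s), "negative")
  expect_error(circuit_rhs(numeric(12)), "13")
})

test_that("trajectories respect non-negativity and source/decay bounds", {
  p <- default_params()
  traj <- integrate_circuit(p, canonical_30h(), opts = fast_opts())
  expect_true(all(traj$states >= -1e-9 * max(traj$states)))
  pv <- expand_params(p)
  z_bound <- p$k34 * p$F_tot / p$d_Z
  phi_bound <- p$gamma / (p$k_sec + p$d_p)
  expect_true(all(traj$states[, "Z3"] <= z_bound * (1 + 1e-9)))
  expect_true(all(traj$states[, "Z4"] <= z_bound * (1 + 1e-9)))
  expect_true(all(traj$states[, "phi_x"] <= phi_bound * (1 + 1e-9)))
  expect_true(all(traj$states[, "F3"] <= p$F_tot * (1 + 1e-9)))
})
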