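# Reduced grids/horizons keep these tests fast; the acceptance suite runs
# the full settings (20-point k scan, 300-h horizons).

small_grid <- function() default_ic_grid(n = 3)

test_that("slow clearance latches, fast clearance relaxes to the diagonal", {
  p <- default_params()
  bi <- classify_stability(set_param(p, "k_alpha_deg", 0.134),
                           ic_grid = small_grid(), horizon_h = 200)
  expect_equal(bi$classification, "bistable")
  expect_equal(nrow(bi$equilibria), 2L)
  # mirror pair, separated by far more than the clustering threshold
  e <- bi$equilibria
  expect_equal(unname(e[1, "X_med"]), unname(e[2, "Y_med"]),
               tolerance = 1e-3)
  expect_equal(unname(e[1, "Y_med"]), unname(e[2, "X_med"]),
               tolerance = 1e-3)
  expect_gt(max(e[1, ]) / min(e[1, ]), 10)

  mono <- classify_stability(set_param(p, "k_alpha_deg", 30),
                             ic_grid = small_grid(), horizon_h = 200)
  expect_equal(mono$classification, "monostable")
  expect_equal(nrow(mono$equilibria), 1L)
  eq <- mono$equilibria[1, ]
  expect_lt(abs(log10(eq["X_med"] / eq["Y_med"])), log10(1.05))
})

test_that("without engageable repression the loop cannot latch", {
  p <- set_param(default_params(), "beta_c", 1e-3) # repression never engages
  rep <- classify_stability(p, ic_grid = small_grid(), horizon_h = 100)
  expect_equal(rep$classification, "monostable")
  eq <- rep$equilibria[1, ]
  expect_lt(abs(log10(eq["X_med"] / eq["Y_med"])), log10(1.05))
})

test_that("classification is invariant to ic_grid permutation", {
  p <- set_param(default_params(), "k_alpha_deg", 0.134)
  g <- small_grid()
  set.seed(11)
  perm <- sample(nrow(g))
  a <- classify_stability(p, ic_grid = g, horizon_h = 150)
  b <- classify_stability(p, ic_grid = g[perm, ], horizon_h = 150)
  expect_equal(a$classification, b$classification)
  expect_equal(sort(a$equilibria), sort(b$equilibria), tolerance = 1e-6)
  # identical partition of the initial conditions, up to label swap
  same_group <- outer(a$basin[perm], a$basin[perm], "==")
  same_group_b <- outer(b$basin, b$basin, "==")
  expect_identical(same_group, same_group_b)
})

test_that("memory time saturates when bistable and is 0 without a write", {
  p <- default_params()
  expect_equal(memory_time(p), 720) # full hold window, latched
  # no activation input: phi stays 0, never negative
  p0 <- set_param(p, "input_conc", 0)
  expect_equal(memory_time(p0), 0)
})

test_that("memory is longer closer to the bistable window", {
  p <- default_params()
  mt <- vapply(c(9, 100), function(k)
    memory_time(set_param(p, "k_alpha_deg", k),
                opts = solver_opts(rtol = 1e-8, save_dt = 60)),
    numeric(1))
  expect_gt(mt[1], mt[2])
  expect_lt(mt[2], 720)
})

test_that("bisection brackets the upper stability boundary", {
  p <- default_params()
  b <- bistability_boundary(p, 1, 50, tol = 0.05, horizon_h = 150,
                            ic_grid = small_grid())
  expect_gt(b, 1)
  expect_lt(b, 50)
  # decisive classification away from the boundary on both sides
  lo <- classify_stability(set_param(p, "k_alpha_deg", b / 3),
                           ic_grid = small_grid(), horizon_h = 300)
  hi <- classify_stability(set_param(p, "k_alpha_deg", b * 5),
                           ic_grid = small_grid(), horizon_h = 300)
  expect_equal(lo$classification, "bistable")
  expect_equal(hi$classification, "monostable")
  # the instability-sign probe agrees close to the boundary
  expect_true(srlatch:::.diagonal_unstable(
    set_param(p, "k_alpha_deg", b * 0.8), horizon_h = 300))
  expect_false(srlatch:::.diagonal_unstable(
    set_param(p, "k_alpha_deg", b * 1.25), horizon_h = 300))
  expect_error(bistability_boundary(p, 20, 50, tol = 0.05,
                                    horizon_h = 150,
                                    ic_grid = small_grid()),
               "same classification")
})
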