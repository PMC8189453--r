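test_that("no-flux Laplacian matches the hand stencil", {
  expect_equal(laplacian_noflux(rep(3, 7), 0.1), rep(0, 7))

  # linear ramp: zero in the interior, bent only at the boundaries
  x <- (1:10 - 0.5) / 10
  lap <- laplacian_noflux(2 + 3 * x, 0.1)
  expect_equal(lap[2:9], rep(0, 8))
  expect_lt(lap[10], 0)
  expect_gt(lap[1], 0)

  # spike at the ventral end with ghost reflection
  lap <- laplacian_noflux(c(1, 0, 0, 0), 1 / 50)
  expect_equal(lap[1], -2500)
  expect_equal(lap[2], 2500)
  expect_error(laplacian_noflux(1, 0.1), "at least 2")
})

test_that("solver configuration rejects inconsistent settings", {
  expect_error(solver_config(steady_tol = 0))
  expect_error(solver_config(t_max = 1, check_interval = 10))
})

test_that("single-compartment oracle has the closed-form Toll-free state", {
  p <- dl_params()
  s0 <- single_compartment_steady_state(p, toll_total = 0)
  expect_equal(s0[["nDl0"]] / s0[["cDl0"]], p$k3 / p$k4, tolerance = 1e-10)
  expect_equal(s0[["nDlstar"]], 0)
  expect_equal(s0[["DlCT"]], 0)
  # total-Cactus balance: synthesis equals the two degradation routes
  expect_equal(p$k1 * s0[["cDl0"]],
               p$k2 * s0[["Cf"]] + p$k10 * s0[["Cub"]], tolerance = 1e-10)
  # Dorsal conservation
  expect_equal(s0[["cDl0"]] + s0[["nDl0"]] + s0[["DlC"]], p$Dl_tot,
               tolerance = 1e-10)
})

test_that("PDE solver agrees with the algebraic oracle on one compartment", {
  p <- dl_params()
  T0 <- toll_profile(dl_grid(1), p$toll_amp, p$toll_sigma)
  oracle <- single_compartment_steady_state(p, T0)
  tight <- solver_config(rel_tol = 1e-11, abs_tol = 1e-13,
                         steady_tol = 1e-12)
  pde <- steady_state(p, dl_grid(1), tight)
  expect_lt(max(abs(pde$state$conc[1, ] - oracle) / pmax(abs(oracle), 1e-30)),
            1e-8)
  # Cactus balance at steady state, summed stoichiometry
  s <- pde$state$conc[1, ]
  expect_equal(p$k1 * s[["cDl0"]],
               p$k2 * s[["Cf"]] + p$k10 * s[["Cub"]], tolerance = 1e-8)
})

test_that("Toll-null runs are flat and reduce to the direct-flow balance", {
  p <- dl_params(toll_amp = 0)
  tight <- solver_config(rel_tol = 1e-11, abs_tol = 1e-13,
                         steady_tol = 1e-12)
  ss <- steady_state(p, dl_grid(10), tight)
  conc <- ss$state$conc
  expect_equal(max(conc[, "nDlstar"]), 0, tolerance = 1e-12)
  # flat: every compartment identical
  expect_lt(max(apply(conc, 2, function(v) diff(range(v)))), 1e-9)
  expect_equal(unname(conc[1, "nDl0"] / conc[1, "cDl0"]), p$k3 / p$k4,
               tolerance = 1e-6)
  # matches the well-mixed oracle
  oracle <- single_compartment_steady_state(p, 0)
  expect_lt(max(abs(conc[1, ] - oracle) / pmax(abs(oracle), 1e-12)), 1e-6)
})

test_that("wild-type steady state converges with conserved totals", {
  ss <- wt_ss()
  expect_true(ss$converged)
  p <- dl_params()
  g <- ss$grid
  # Dorsal grand total: no drift relative to the initial condition
  expect_equal(dl_grand_total(ss$state), g$n * p$Dl_tot,
               tolerance = 1e-6)
  # per-compartment Toll conservation against the initial profile
  T_init <- toll_profile(g, p$toll_amp, p$toll_sigma)
  T_now <- ss$state$conc[, "T"] + ss$state$conc[, "DlCT"]
  expect_lt(max(abs(T_now - T_init) / T_init), 1e-8)
  # monotone non-increasing nuclear gradient
  expect_true(all(diff(derived_totals(ss$state)$nDl_total) <= 1e-9))
})

test_that("steady state is independent of the integrator", {
  p <- dl_params()
  g <- dl_grid(25)
  a <- steady_state(p, g, solver_config(method = "bdf"))
  b <- steady_state(p, g, solver_config(method = "lsoda"))
  expect_lt(max(abs(a$state$conc - b$state$conc) /
                  pmax(abs(a$state$conc), 1e-6)), 1e-6)
  # compiled and reference rhs give the same fixed point
  c2 <- steady_state(p, g, use_compiled = FALSE)
  expect_lt(max(abs(a$state$conc - c2$state$conc) /
                  pmax(abs(a$state$conc), 1e-6)), 1e-6)
})

test_that("compiled and reference rhs agree under the structural switches", {
  g <- dl_grid(10)
  cfg <- solver_config(rel_tol = 1e-10, abs_tol = 1e-12)
  for (p in list(dl_params(),
                 dl_params(synthesis_driver = "cDl_total"),
                 dl_params(toll_recycling = "consumed"),
                 dl_params(k12_destination = "cDlstar"))) {
    a <- integrate_model(p, g, t_end = 50, config = cfg,
                         use_compiled = TRUE)
    b <- integrate_model(p, g, t_end = 50, config = cfg,
                         use_compiled = FALSE)
    expect_lt(max(abs(a$conc - b$conc) / pmax(abs(a$conc), 1e-6)), 1e-6)
  }
})

test_that("grid refinement changes the gradient by less than 1%", {
  p <- dl_params()
  co <- solver_config()
  a <- steady_state(p, dl_grid(50), co)
  b <- steady_state(p, dl_grid(100), co)
  fa <- nDl_profile(a); fb <- nDl_profile(b)
  interp <- stats::approx(fb$position, fb$nDl, xout = fa$position,
                          rule = 2)$y
  expect_lt(max(abs(interp - fa$nDl)) / max(fa$nDl), 0.01)
})

test_that("hitting t_max raises a diagnosable non-convergence error", {
  p <- dl_params()
  cfg <- solver_config(t_max = 2, check_interval = 1, steady_tol = 1e-14)
  err <- tryCatch(steady_state(p, dl_grid(5), cfg),
                  dl_no_convergence = function(e) e)
  expect_s3_class(err, "dl_no_convergence")
  expect_true(is.finite(err$residual))
})
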