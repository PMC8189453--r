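test_that("scenarios apply overrides then multipliers without side effects", {
  base <- dl_params()
  dl6 <- apply_scenario(base, scenario_presets()$dl6_plus)
  expect_equal(dl6$Dl_tot, 0.4605)
  unchanged <- setdiff(dl_param_names(), "Dl_tot")
  expect_equal(unlist(dl6[unchanged]), unlist(base[unchanged]))
  expect_equal(base$Dl_tot, 0.525)  # base untouched

  empty <- dl_scenario("noop")
  expect_equal(unlist(apply_scenario(base, empty)[dl_param_names()]),
               unlist(base[dl_param_names()]))

  pll <- dl_scenario("pll_partial", multipliers = list(k9 = 0.5, k10 = 0.5))
  halved <- apply_scenario(base, pll)
  expect_equal(halved$k9, 0.0018)
  expect_equal(halved$k10, 213.5)

  expect_error(dl_scenario("bad", overrides = list(k99 = 1)), "unknown")
  expect_error(dl_scenario("bad", overrides = list(k9 = 1),
                           multipliers = list(k9 = 2)), "both")
})

test_that("nuclear decomposition splits the gradient into its two routes", {
  d <- decompose_nuclear(wt_ss())
  expect_equal(d$nDl_total, d$nDl0 + d$nDlstar)

  # direct flow is uniform along the axis (within 5% relative variation)
  expect_lt(diff(range(d$nDl0)) / mean(d$nDl0), 0.05)

  # dorsally the direct route dominates the Toll route
  n <- nrow(d)
  expect_lt(d$nDlstar[n], 0.05 * d$nDl0[n])

  # Toll-null embryos have no Toll-route nuclear Dorsal at all
  ss0 <- steady_state(dl_params(toll_amp = 0), dl_grid(10))
  d0 <- decompose_nuclear(ss0)
  expect_equal(max(d0$nDlstar), 0, tolerance = 1e-12)
  expect_equal(d0$nDl_total, d0$nDl0)
})

test_that("total-Cactus fractions reproduce the genotype table", {
  wt <- wt_ss()
  expect_equal(cactus_total_fraction(wt, wt), 100)
  expect_equal(cactus_total_fraction(genotype_ss("dl6_plus"), wt),
               90.70, tolerance = 1 / 90.7)
  expect_equal(cactus_total_fraction(genotype_ss("cactA2_cact011"), wt),
               53.40, tolerance = 1 / 53.4)
  expect_equal(cactus_total_fraction(genotype_ss("dl6_cactA2"), wt),
               71.80, tolerance = 1 / 71.8)
})

test_that("species percent change selects region and species correctly", {
  wt <- wt_ss()
  for (sp in c("cDl0", "DlC", "nDlstar")) {
    expect_equal(species_percent_change(wt, wt, sp, "ventral"), 0)
    expect_equal(species_percent_change(wt, wt, sp, "mean"), 0)
  }
  # lowering total Dorsal lowers the trimer everywhere
  expect_lt(species_percent_change(genotype_ss("dl6_plus"), wt,
                                   "DlC", "mean"), 0)
  expect_error(species_percent_change(wt, wt, "nosuch"), "'arg'")
})

test_that("gradient metrics recover analytic shape descriptors", {
  flat <- tibble::tibble(position = (1:10 - 0.5) / 10, nDl = 0.7)
  m <- gradient_metrics(flat)
  expect_equal(m$peak, 0.7)
  expect_equal(m$basal, 0.7)
  expect_equal(m$amplitude, 0)
  expect_equal(m$max_slope, 0)

  # Gaussian of width 0.2: steepest at x = 0.2 with |slope| exp(-1/2)/0.2
  x <- (1:50 - 0.5) / 50
  gauss <- tibble::tibble(position = x, nDl = exp(-x^2 / (2 * 0.2^2)))
  m <- gradient_metrics(gauss)
  expect_equal(m$max_slope, exp(-0.5) / 0.2, tolerance = 0.03)
  pos_at_max <- m$slope_profile$position[which.max(abs(m$slope_profile$slope))]
  expect_equal(pos_at_max, 0.2, tolerance = 0.05)

  expect_error(gradient_metrics(flat[1:2, ]), "at least 3")
})

test_that("cact hypomorphs show the dual effect with the crossover at
           the route-balance point", {
  wt <- wt_ss()
  mu <- genotype_ss("cactA2_cact011")
  nd_wt <- derived_totals(wt$state)$nDl_total
  nd_mu <- derived_totals(mu$state)$nDl_total
  n <- length(nd_wt)
  expect_lt(nd_mu[1], nd_wt[1])   # less nuclear Dorsal ventrally
  expect_gt(nd_mu[n], nd_wt[n])   # more dorsally

  # position where the mutant crosses wild type
  cross_genotype <- which(diff(sign(nd_mu - nd_wt)) != 0)[1]
  # position where the mutant's two entry routes balance
  d <- decompose_nuclear(mu)
  cross_routes <- which(diff(sign(d$nDlstar - d$nDl0)) != 0)[1]
  expect_lt(abs(cross_genotype - cross_routes), 3)
})

test_that("dl6/+ lowers the peak but spares the dorsal side", {
  wt <- wt_ss()
  mu <- genotype_ss("dl6_plus")
  nd_wt <- derived_totals(wt$state)$nDl_total
  nd_mu <- derived_totals(mu$state)$nDl_total
  n <- length(nd_wt)
  expect_lt(nd_mu[1], 0.95 * nd_wt[1])
  # free Dorsal (and hence direct-flow nuclear Dorsal) drops by about
  # a tenth, far less than the ventral peak
  expect_lt(abs(nd_mu[n] - nd_wt[n]) / nd_wt[n], 0.10)
})

test_that("gradient slopes order wild type above the double mutant", {
  slopes <- vapply(
    list(wt_ss(), genotype_ss("dl6_plus"), genotype_ss("cactA2_cact011"),
         genotype_ss("dl6_cactA2")),
    function(ss) gradient_metrics(nDl_profile(ss))$max_slope,
    numeric(1))
  names(slopes) <- c("WT", "dl6_plus", "cactA2_cact011", "dl6_cactA2")
  expect_equal(names(which.max(slopes)), "WT")
  expect_equal(names(which.min(slopes)), "dl6_cactA2")
})

test_that("parameter sweeps preserve order and expose monotone responses", {
  p <- dl_params()
  g <- dl_grid(25)
  sw <- parameter_sweep(p, "Dl_tot", c(0.8, 0.6, 0.4, 0.2), g)
  peaks <- dplyr::summarise(dplyr::group_by(sw, factor),
                            peak = nDl_total[1])
  # order preserved, and the ventral peak falls with the factor
  expect_equal(peaks$factor, c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(diff(peaks$peak) > 0))

  states <- attr(sw, "states")
  expect_length(states, 4)
  expect_s3_class(states[[1]], "dl_steady_state")
})

test_that("silencing the signalling step flattens the gradient at the
           dorsal level with ventral DlCT accumulation", {
  p <- dl_params()
  g <- dl_grid(25)
  wt <- steady_state(p, g)
  sw <- parameter_sweep(p, c("k9", "k10"), 0, g)
  pll <- attr(sw, "states")[[1]]
  nd <- derived_totals(pll$state)$nDl_total
  nd_wt <- derived_totals(wt$state)$nDl_total
  expect_lt(diff(range(nd)) / mean(nd), 0.01)      # flat
  expect_equal(nd[1], nd_wt[g$n], tolerance = 0.10) # near the WT dorsal level
  expect_gt(pll$state$conc[1, "DlCT"], wt$state$conc[1, "DlCT"])
})
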