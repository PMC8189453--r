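#' Mutant / perturbation scenarios
#'
#' A scenario is a named set of parameter changes: `overrides` replace a
#' parameter by an absolute value, `multipliers` scale it. A parameter
#' may appear in at most one of the two maps.
#'
#' @param name Scenario label.
#' @param overrides Named list of parameter -> absolute value.
#' @param multipliers Named list of parameter -> scale factor.
#' @return An object of class `dl_scenario`.
#' @examples
#' dl_scenario("dl6_plus", overrides = list(Dl_tot = 0.4605))
#' dl_scenario("pll_partial", multipliers = list(k9 = 0.5, k10 = 0.5))
#' @export
dl_scenario <- function(name, overrides = list(), multipliers = list()) {
  overrides <- as.list(overrides)
  multipliers <- as.list(multipliers)
  known <- dl_param_names()
  bad <- setdiff(c(names(overrides), names(multipliers)), known)
  if (length(bad) > 0) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- intersect(names(overrides), names(multipliers))
  if (length(dup) > 0) {
    stop("parameter(s) in both overrides and multipliers: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, overrides = overrides,
                 multipliers = multipliers), class = "dl_scenario")
}

#' @export
print.dl_scenario <- function(x, ...) {
  fmt <- function(l) if (length(l) == 0) "-" else
    paste(names(l), unlist(l), sep = "=", collapse = ", ")
  cat(sprintf("<dl_scenario> %s | overrides: %s | multipliers: %s\n",
              x$name, fmt(x$overrides), fmt(x$multipliers)))
  invisible(x)
}

#' Bundled genotype scenarios
#'
#' The three mutant genotypes quantified alongside wild type, plus two
#' canonical perturbations. `dl6_plus` lowers total Dorsal only;
#' `cactA2_cact011` lowers the Cactus synthesis constant k1 only;
#' `dl6_cactA2` lowers both (total Cactus is an output of these inputs,
#' not itself an input). `toll_null` removes Toll activation;
#' `pll_null` silences the signalling step (k9 = k10 = 0 is represented
#' by multiplier 0).
#'
#' @return Named list of [dl_scenario()] objects.
#' @export
scenario_presets <- function() {
  list(
    dl6_plus = dl_scenario("dl6_plus", overrides = list(Dl_tot = 0.4605)),
    cactA2_cact011 = dl_scenario("cactA2_cact011",
                                 overrides = list(k1 = 0.1825)),
    dl6_cactA2 = dl_scenario("dl6_cactA2",
                             overrides = list(Dl_tot = 0.375, k1 = 0.500)),
    toll_null = dl_scenario("toll_null", overrides = list(toll_amp = 0)),
    pll_null = dl_scenario("pll_null",
                           multipliers = list(k9 = 0, k10 = 0))
  )
}

#' Apply a scenario to a base parameter set
#'
#' Overrides are applied first, then multipliers; the base object is
#' untouched. Multiplier 0 is allowed (e.g. Toll-null or pll-null
#' perturbations) even where the constructor would reject an explicit
#' zero, because the zeroed constant simply silences its reactions.
#'
#' @param base A [dl_params()] object.
#' @param scenario A [dl_scenario()].
#' @return A new [dl_params()]-classed object.
#' @examples
#' apply_scenario(dl_params(), scenario_presets()$dl6_plus)$Dl_tot
#' @export
apply_scenario <- function(base, scenario) {
  stopifnot(inherits(base, "dl_params"), inherits(scenario, "dl_scenario"))
  p <- unclass(base)
  for (nm in names(scenario$overrides)) p[[nm]] <- scenario$overrides[[nm]]
  for (nm in names(scenario$multipliers)) {
    p[[nm]] <- p[[nm]] * scenario$multipliers[[nm]]
  }
  vals <- unlist(p[dl_param_names()])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("scenario produced negative or non-finite parameters",
         call. = FALSE)
  }
  structure(p, class = "dl_params")
}

#' Full species profile of a steady state
#'
#' @param ss A `dl_steady_state` from [steady_state()].
#' @return A tibble with columns `position`, `nDl_total`, `nDl0`,
#'   `nDlstar`, `cDl0`, `cDlstar`, `Cf`, `Cub`, `DlC`, `DlCT`, `T`.
#' @export
steady_profile <- function(ss) {
  stopifnot(inherits(ss, "dl_steady_state"))
  m <- ss$state$conc
  tibble::tibble(
    position = ss$grid$positions,
    nDl_total = m[, "nDl0"] + m[, "nDlstar"],
    nDl0 = m[, "nDl0"], nDlstar = m[, "nDlstar"],
    cDl0 = m[, "cDl0"], cDlstar = m[, "cDlstar"],
    Cf = m[, "Cf"], Cub = m[, "Cub"],
    DlC = m[, "DlC"], DlCT = m[, "DlCT"], T = m[, "T"]
  )
}

#' Nuclear Dorsal gradient of a steady state
#'
#' @param ss A `dl_steady_state`.
#' @return A gradient-profile tibble with columns `position` and `nDl`.
#' @export
nDl_profile <- function(ss) {
  pr <- steady_profile(ss)
  tibble::tibble(position = pr$position, nDl = pr$nDl_total)
}

#' Decompose nuclear Dorsal into its two entry routes
#'
#' Splits the observable nuclear gradient into Dorsal imported by
#' Toll-independent direct flow (`nDl0`) and by the Toll-activated route
#' (`nDlstar`); their sum is `nDl_total`.
#'
#' @param state A [dl_state()] or `dl_steady_state`.
#' @return A tibble with columns `position`, `nDl0`, `nDlstar`,
#'   `nDl_total`.
#' @export
decompose_nuclear <- function(state) {
  if (inherits(state, "dl_steady_state")) state <- state$state
  stopifnot(inherits(state, "dl_state"))
  m <- state$conc
  tibble::tibble(position = state$grid$positions,
                 nDl0 = m[, "nDl0"], nDlstar = m[, "nDlstar"],
                 nDl_total = m[, "nDl0"] + m[, "nDlstar"])
}

as_dl_state <- function(x) {
  if (inherits(x, "dl_steady_state")) x$state
  else if (inherits(x, "dl_state")) x
  else stop("expected a dl_state or dl_steady_state", call. = FALSE)
}

#' Total Cactus of a mutant as a percentage of wild type
#'
#' Total Cactus is the sum over compartments of every Cactus-containing
#' species (`Cf + Cub + DlC + DlCT`).
#'
#' @param mutant_state,wt_state States (or steady-state objects) on the
#'   same grid.
#' @return Percentage (100 = wild-type level).
#' @export
cactus_total_fraction <- function(mutant_state, wt_state) {
  m <- as_dl_state(mutant_state); w <- as_dl_state(wt_state)
  if (m$grid$n != w$grid$n) stop("states are on different grids",
                                 call. = FALSE)
  ctot <- function(s) sum(derived_totals(s)$C_total)
  denom <- ctot(w)
  if (denom <= 0) stop("wild-type total Cactus is zero", call. = FALSE)
  100 * ctot(m) / denom
}

#' Signed percent change of one species between genotypes
#'
#' @param mutant_state,wt_state States (or steady-state objects) on the
#'   same grid.
#' @param species One of [dl_species()].
#' @param region `"ventral"` (ventral-most compartment), `"dorsal"`
#'   (dorsal-most) or `"mean"` (unweighted spatial mean).
#' @return `100 * (mutant - wt) / wt` for the selected readout.
#' @examples
#' \donttest{
#' wt <- steady_state(dl_params())
#' mu <- steady_state(apply_scenario(dl_params(),
#'                                   scenario_presets()$dl6_plus))
#' species_percent_change(mu, wt, "DlC", "mean")
#' }
#' @export
species_percent_change <- function(mutant_state, wt_state, species,
                                   region = c("ventral", "dorsal", "mean")) {
  region <- match.arg(region)
  species <- match.arg(species, dl_species())
  m <- as_dl_state(mutant_state); w <- as_dl_state(wt_state)
  if (m$grid$n != w$grid$n) stop("states are on different grids",
                                 call. = FALSE)
  pick <- function(s) {
    v <- s$conc[, species]
    switch(region, ventral = v[1], dorsal = v[length(v)], mean = mean(v))
  }
  ref <- pick(w)
  if (ref == 0) stop("wild-type value is zero for species ", species,
                     call. = FALSE)
  100 * (pick(m) - ref) / ref
}

#' Shape metrics of a nuclear-Dorsal gradient
#'
#' Reads the ventral peak, dorsal basal level and amplitude directly
#' from the profile ends and computes the spatial derivative by central
#' differences (one-sided at the ends); the highest slope is the
#' maximum absolute derivative, a readout of how sharply neighbouring
#' nuclei differ.
#'
#' @param profile A tibble with columns `position` and `nDl` (as from
#'   [nDl_profile()] or the synthetic generators), at least 3 rows.
#' @return An object of class `dl_gradient_metrics`: list with `peak`,
#'   `basal`, `amplitude`, `max_slope` and a `slope_profile` tibble
#'   (`position`, `slope`).
#' @export
gradient_metrics <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("position", "nDl") %in% names(profile)))
  x <- profile$position
  y <- profile$nDl
  n <- length(x)
  if (n < 3) stop("at least 3 positions are required", call. = FALSE)
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing",
                              call. = FALSE)
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    slope[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  }
  structure(list(peak = y[1], basal = y[n], amplitude = y[1] - y[n],
                 max_slope = max(abs(slope)),
                 slope_profile = tibble::tibble(position = x, slope = slope)),
            class = "dl_gradient_metrics")
}

#' @export
print.dl_gradient_metrics <- function(x, ...) {
  cat(sprintf(paste0("<dl_gradient_metrics> peak %.4g, basal %.4g, ",
                     "amplitude %.4g, max |slope| %.4g\n"),
              x$peak, x$basal, x$amplitude, x$max_slope))
  invisible(x)
}

#' @export
tidy.dl_gradient_metrics <- function(x, ...) {
  tibble::tibble(metric = c("peak", "basal", "amplitude", "max_slope"),
                 value = c(x$peak, x$basal, x$amplitude, x$max_slope))
}

#' Run a scenario and compare it with wild type
#'
#' Convenience wrapper: applies the scenario, integrates both genotypes
#' to steady state (the wild-type run may be supplied to avoid
#' recomputation) and assembles the comparison readouts.
#'
#' @param scenario A [dl_scenario()].
#' @param base Wild-type parameters.
#' @param grid,config Grid and solver configuration.
#' @param wt_ss Optional precomputed wild-type `dl_steady_state`.
#' @return List with the mutant steady state (`ss`), the scenario,
#'   `cactus_total_pct`, a `metrics` object for the mutant nuclear
#'   gradient and the two-genotype `profiles` tibble (long, with a
#'   `genotype` column).
#' @export
run_scenario <- function(scenario, base = dl_params(), grid = dl_grid(),
                         config = solver_config(), wt_ss = NULL) {
  stopifnot(inherits(scenario, "dl_scenario"))
  if (is.null(wt_ss)) wt_ss <- steady_state(base, grid, config)
  mu_ss <- steady_state(apply_scenario(base, scenario), grid, config)
  profiles <- dplyr::bind_rows(
    dplyr::mutate(steady_profile(wt_ss), genotype = "WT"),
    dplyr::mutate(steady_profile(mu_ss), genotype = scenario$name)
  )
  list(ss = mu_ss, wt_ss = wt_ss, scenario = scenario,
       cactus_total_pct = cactus_total_fraction(mu_ss, wt_ss),
       metrics = gradient_metrics(nDl_profile(mu_ss)),
       profiles = profiles)
}

#' Steady-state sweep over scale factors of one parameter
#'
#' Runs one steady-state simulation per factor (order preserved),
#' scaling `target` by each factor relative to `base`. Factor 0 is
#' allowed (e.g. Toll-null, or silencing the signalling step).
#'
#' @param base A [dl_params()] object.
#' @param target Parameter name to scale, or a character vector of
#'   names scaled jointly by the same factor (e.g. `c("k9", "k10")`).
#' @param factors Numeric vector of non-negative scale factors.
#' @param grid,config Grid and solver configuration.
#' @return A tibble of full species profiles with a leading `factor`
#'   column; the converged states are attached as the `"states"`
#'   attribute (a named list).
#' @export
parameter_sweep <- function(base, target, factors, grid = dl_grid(),
                            config = solver_config()) {
  stopifnot(inherits(base, "dl_params"), length(factors) >= 1,
            all(is.finite(factors)), all(factors >= 0))
  target <- match.arg(target, dl_param_names(), several.ok = TRUE)
  states <- vector("list", length(factors))
  rows <- vector("list", length(factors))
  for (i in seq_along(factors)) {
    sc <- dl_scenario(sprintf("%s_x%g", paste(target, collapse = "_"),
                              factors[i]),
                      multipliers = stats::setNames(
                        as.list(rep(factors[i], length(target))), target))
    ss <- tryCatch(
      steady_state(apply_scenario(base, sc), grid, config),
      dl_no_convergence = function(e) {
        stop("sweep factor ", factors[i], " did not converge: ",
             conditionMessage(e), call. = FALSE)
      })
    states[[i]] <- ss
    rows[[i]] <- dplyr::mutate(steady_profile(ss), factor = factors[i],
                               .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "states") <- stats::setNames(states, paste0("factor_", factors))
  out
}
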