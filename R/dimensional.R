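#' Effective nuclear-import constant
#'
#' Dorsal enters nuclei by two routes with very different rate
#' constants (k3 for direct flow, k11 for the Toll route). The
#' effective import constant is their concentration-weighted average,
#' weighted by the cytoplasmic pools feeding each route (`cDl0` and
#' `cDlstar`), evaluated at the ventral-most compartment of the
#' steady state where both routes operate.
#'
#' @param wt_state A [dl_state()] or `dl_steady_state` at steady state.
#' @param params The [dl_params()] used for the run.
#' @return Dimensionless rate `(k3*cDl0 + k11*cDlstar) / (cDl0 +
#'   cDlstar)`; always between k3 and k11.
#' @export
effective_import_constant <- function(wt_state, params) {
  stopifnot(inherits(params, "dl_params"))
  st <- as_dl_state(wt_state)
  cDl0 <- unname(st$conc[1, "cDl0"])
  cDls <- unname(st$conc[1, "cDlstar"])
  denom <- cDl0 + cDls
  if (denom <= 0) stop("ventral cytoplasmic Dorsal is zero", call. = FALSE)
  (params$k3 * cDl0 + params$k11 * cDls) / denom
}

#' Dimensional characteristic-time interval
#'
#' The model is fitted to steady states only, so its characteristic
#' time must be anchored to an independently timed process. Using the
#' literature range for Dorsal nuclear-import time (2 to 5 minutes),
#' the effective import rate must equal 1/(import time); the model's
#' characteristic time is therefore `k_eff` times the import-time
#' interval.
#'
#' @param k_eff Effective dimensionless import constant, from
#'   [effective_import_constant()].
#' @param import_time_bounds_s Literature nuclear-import time interval
#'   in seconds (default `c(120, 300)`).
#' @return Named numeric `c(lower, upper)` in seconds.
#' @examples
#' time_scale(0.0373)   # about (4.5, 11.19) s
#' @export
time_scale <- function(k_eff, import_time_bounds_s = c(120, 300)) {
  stopifnot(is.finite(k_eff), k_eff > 0,
            length(import_time_bounds_s) == 2,
            all(import_time_bounds_s > 0),
            import_time_bounds_s[1] < import_time_bounds_s[2])
  stats::setNames(k_eff * import_time_bounds_s, c("lower_s", "upper_s"))
}

#' Convert a dimensionless diffusivity to physical units
#'
#' Multiplies by the squared half-embryo length and divides by the
#' characteristic-time interval; because time appears in the
#' denominator, the upper time bound gives the lower diffusivity bound
#' and vice versa.
#'
#' @param D_dimless Dimensionless diffusivity (half-embryo lengths
#'   squared per characteristic time).
#' @param t_char_bounds_s Characteristic-time interval in seconds, from
#'   [time_scale()].
#' @param L_half_um Embryo half-length in micrometres (default 245).
#' @return Named numeric `c(lower, upper)` in um^2/s.
#' @examples
#' dimensional_diffusion(3.39e-5, time_scale(0.0373))
#' @export
dimensional_diffusion <- function(D_dimless, t_char_bounds_s,
                                  L_half_um = 245) {
  stopifnot(D_dimless >= 0, length(t_char_bounds_s) == 2,
            all(t_char_bounds_s > 0), L_half_um > 0)
  t_char_bounds_s <- sort(as.numeric(t_char_bounds_s))
  stats::setNames(D_dimless * L_half_um^2 / rev(t_char_bounds_s),
                  c("lower_um2_s", "upper_um2_s"))
}

#' Lateral transport coefficient
#'
#' One-dimensional diffusive length `sqrt(2 D t)` over a given
#' duration, expressed in units of compartment width: the number of
#' nucleo-cytoplasmic compartments a species traverses.
#'
#' @param D_um2_s Diffusivity in um^2/s.
#' @param compartment_um Compartment width in micrometres (default
#'   245/50).
#' @param duration_s Duration in seconds (default 90 minutes).
#' @return Compartments traversed (dimensionless).
#' @examples
#' transport_coefficient(0.18)
#' @export
transport_coefficient <- function(D_um2_s, compartment_um = 245 / 50,
                                  duration_s = 90 * 60) {
  stopifnot(D_um2_s >= 0, compartment_um > 0, duration_s > 0)
  sqrt(2 * D_um2_s * duration_s) / compartment_um
}

#' Trimer diffusion versus its reaction rates
#'
#' Compares the rate at which the Dorsal-Cactus trimer hops between
#' adjacent compartments (`D_DlC / dx^2`) with the kinetic constants
#' that remove it: nuclear import of released Dorsal (k11) and
#' dissociation back to the free forms (k6). When the hop rate is much
#' smaller than both, the trimer reacts essentially in place and the
#' signalling-complex gradient tracks the Toll activation profile.
#'
#' @param params A [dl_params()] object.
#' @param grid A [dl_grid()].
#' @return List with `ratio` (= `D_DlC / dx^2`), `k11`, `k6` and the
#'   logical flags `slower_than_k11`, `slower_than_k6`.
#' @examples
#' dlc_diffusion_vs_rates(dl_params(), dl_grid())$ratio  # 0.08475
#' @export
dlc_diffusion_vs_rates <- function(params, grid = dl_grid()) {
  stopifnot(inherits(params, "dl_params"), inherits(grid, "dl_grid"))
  ratio <- params$D_DlC / grid$dx^2
  list(ratio = ratio, k11 = params$k11, k6 = params$k6,
       slower_than_k11 = ratio < params$k11,
       slower_than_k6 = ratio < params$k6)
}

#' Dimensional report for a converged wild-type run
#'
#' Chains the dimensional analysis: effective import constant,
#' characteristic-time interval, and dimensional diffusivity intervals
#' and transport coefficients for the three diffusing species.
#'
#' @param wt_ss A wild-type `dl_steady_state`.
#' @param import_time_bounds_s,L_half_um See [time_scale()] and
#'   [dimensional_diffusion()].
#' @param duration_s Duration for the transport coefficient.
#' @return List with `k_eff`, `t_char_bounds_s` and a `diffusion`
#'   tibble (`species`, `D_dimless`, `D_lower_um2_s`, `D_upper_um2_s`,
#'   `transport_lower`, `transport_upper`).
#' @export
dimensional_report <- function(wt_ss, import_time_bounds_s = c(120, 300),
                               L_half_um = 245, duration_s = 90 * 60) {
  stopifnot(inherits(wt_ss, "dl_steady_state"))
  params <- wt_ss$params
  k_eff <- effective_import_constant(wt_ss, params)
  tc <- time_scale(k_eff, import_time_bounds_s)
  comp_um <- L_half_um / wt_ss$grid$n
  species <- c(cDl0 = "D_Dl", Cf = "D_C", DlC = "D_DlC")
  rows <- purrr::imap(species, function(par, sp) {
    Dd <- params[[par]]
    Di <- dimensional_diffusion(Dd, tc, L_half_um)
    tibble::tibble(species = sp, D_dimless = Dd,
                   D_lower_um2_s = Di[[1]], D_upper_um2_s = Di[[2]],
                   transport_lower = transport_coefficient(Di[[1]], comp_um,
                                                           duration_s),
                   transport_upper = transport_coefficient(Di[[2]], comp_um,
                                                           duration_s))
  })
  list(k_eff = k_eff, t_char_bounds_s = tc,
       diffusion = dplyr::bind_rows(rows))
}
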