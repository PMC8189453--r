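#' Discrete Laplacian with no-flux boundaries
#'
#' Second-order central difference on a uniform grid; the boundary
#' stencils use reflective ghost values (`f[0] = f[1]`,
#' `f[n+1] = f[n]`), which implements zero diffusive flux at both
#' midlines and makes the operator conservative (its sum is exactly 0).
#'
#' @param field Numeric vector (length >= 2) of per-compartment values.
#' @param dx Compartment width.
#' @return Numeric vector of the same length.
#' @examples
#' laplacian_noflux(c(1, 0, 0, 0), dx = 1 / 50)[1:2]
#' @export
laplacian_noflux <- function(field, dx) {
  n <- length(field)
  if (n < 2) stop("field must have at least 2 compartments", call. = FALSE)
  left <- c(field[1], field[-n])
  right <- c(field[-1], field[n])
  (left - 2 * field + right) / dx^2
}

#' Solver configuration
#'
#' @param rel_tol,abs_tol Integration tolerances passed to the stiff
#'   multistep integrator.
#' @param steady_tol Steady-state criterion: the run stops when
#'   `max |d state/dt| <= steady_tol * max(1, max |state|)`.
#' @param t_max Cap on model time before declaring non-convergence.
#' @param check_interval Model time of the first integration chunk;
#'   subsequent chunks double in length so a slow approach costs few
#'   integrator restarts.
#' @param method deSolve integration method. The default `"bdf"` is a
#'   variable-order backward-differentiation multistep scheme; only the
#'   steady state is used downstream, and the result is verified to be
#'   independent of the integrator.
#' @return An object of class `dl_solver_config`.
#' @export
solver_config <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                          steady_tol = 1e-9, t_max = 1e6,
                          check_interval = 1000, method = "bdf") {
  stopifnot(rel_tol > 0, abs_tol > 0, steady_tol > 0,
            check_interval > 0, t_max > check_interval)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 steady_tol = steady_tol, t_max = t_max,
                 check_interval = check_interval, method = method),
            class = "dl_solver_config")
}

# Pack/unpack between the n x 9 concentration matrix and the
# compartment-major vector the integrator uses (species fastest), which
# keeps the Jacobian banded with bandwidth 9.
pack_state <- function(conc) as.vector(t(conc))
unpack_state <- function(y, n) {
  matrix(y, nrow = n, ncol = 9, byrow = TRUE,
         dimnames = list(NULL, dl_species()))
}

compiled_parms <- function(params, grid) {
  c(unlist(params[c(paste0("k", 1:12), "D_Dl", "D_C", "D_DlC")]),
    n = grid$n, dx = grid$dx,
    driver = as.numeric(params$synthesis_driver == "cDl_total"),
    k12dest = as.numeric(params$k12_destination == "cDlstar"),
    tollrec = as.numeric(params$toll_recycling == "consumed"))
}

# One integration chunk; returns the state vector at the chunk end.
integrate_chunk <- function(y, t_len, params, grid, config, use_compiled) {
  if (use_compiled) {
    out <- deSolve::ode(
      y = y, times = c(0, t_len), func = "dlgrad_derivs",
      parms = compiled_parms(params, grid),
      dllname = "dlgradient", initfunc = "dlgrad_initmod",
      method = config$method, rtol = config$rel_tol, atol = config$abs_tol,
      jactype = "bandint", bandup = 9L, banddown = 9L)
  } else {
    rhs_fun <- function(t, y, parms) {
      st <- dl_state(unpack_state(y, grid$n), grid)
      list(pack_state(model_rhs(st, params, grid)$conc))
    }
    out <- deSolve::ode(
      y = y, times = c(0, t_len), func = rhs_fun, parms = NULL,
      method = config$method, rtol = config$rel_tol, atol = config$abs_tol,
      jactype = "bandint", bandup = 9L, banddown = 9L)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("integrator failure in chunk of length ", t_len, call. = FALSE)
  }
  out[nrow(out), -1]
}

#' Integrate the model over a fixed time span
#'
#' Runs the method-of-lines system from [initial_state()] to model time
#' `t_end` and returns the state there. Used for trajectory-level
#' diagnostics (e.g. verifying the compiled right-hand side against
#' [model_rhs()] on configurations whose steady-state approach is
#' slow); steady states come from [steady_state()].
#'
#' @param params A [dl_params()] object.
#' @param grid A [dl_grid()].
#' @param t_end Model time to integrate to (> 0).
#' @param config A [solver_config()] (its tolerances and method are
#'   used; the steady-state settings are ignored).
#' @param use_compiled Use the compiled right-hand side (default).
#' @return A [dl_state()] at `t_end`.
#' @export
integrate_model <- function(params, grid = dl_grid(), t_end,
                            config = solver_config(),
                            use_compiled = TRUE) {
  stopifnot(inherits(params, "dl_params"), inherits(grid, "dl_grid"),
            t_end > 0)
  y <- pack_state(initial_state(params, grid)$conc)
  y <- integrate_chunk(y, t_end, params, grid, config, use_compiled)
  dl_state(unpack_state(y, grid$n), grid)
}

#' Integrate the reaction-diffusion system to steady state
#'
#' Starts from [initial_state()] and integrates the stiff
#' method-of-lines system in geometrically growing time chunks until
#' the residual criterion of [solver_config()] is met. Small negative
#' concentrations within integrator tolerance (magnitude below
#' `max(1e-12, 100 * abs_tol)`) are clipped to zero between chunks;
#' larger negatives abort with a diagnostic.
#'
#' @param params A [dl_params()] object.
#' @param grid A [dl_grid()].
#' @param config A [solver_config()].
#' @param use_compiled Use the compiled right-hand side (default). The
#'   pure-R [model_rhs()] gives the same steady state and is kept as a
#'   cross-check.
#' @return An object of class `dl_steady_state`: list with the final
#'   `state` ([dl_state()]), the `params` and `grid` used, the model
#'   `time` reached, the final `residual` and `converged = TRUE`.
#'   Throws a condition of class `dl_no_convergence` (carrying the
#'   residual) if `t_max` is reached first.
#' @examples
#' \donttest{
#' ss <- steady_state(dl_params())
#' nDl_profile(ss)
#' }
#' @export
steady_state <- function(params, grid = dl_grid(), config = solver_config(),
                         use_compiled = TRUE) {
  stopifnot(inherits(params, "dl_params"), inherits(grid, "dl_grid"),
            inherits(config, "dl_solver_config"))
  y <- pack_state(initial_state(params, grid)$conc)
  t_now <- 0
  chunk <- config$check_interval
  residual <- Inf
  repeat {
    t_len <- min(chunk, config$t_max - t_now)
    y <- integrate_chunk(y, t_len, params, grid, config, use_compiled)
    t_now <- t_now + t_len
    neg <- y < 0
    neg_floor <- -max(1e-12, 100 * config$abs_tol)
    if (any(y < neg_floor)) {
      stop("negative concentrations beyond tolerance (min = ",
           signif(min(y), 3), ") at t = ", t_now, call. = FALSE)
    }
    y[neg] <- 0
    st <- dl_state(unpack_state(y, grid$n), grid)
    residual <- max(abs(model_rhs(st, params, grid)$conc))
    if (residual <= config$steady_tol * max(1, max(abs(y)))) {
      return(structure(list(state = st, params = params, grid = grid,
                            time = t_now, residual = residual,
                            converged = TRUE),
                       class = "dl_steady_state"))
    }
    if (t_now >= config$t_max) {
      cond <- structure(
        class = c("dl_no_convergence", "error", "condition"),
        list(message = sprintf(
          "no steady state by t = %g (residual %.3g)", t_now, residual),
          call = sys.call(-1), residual = residual, time = t_now))
      stop(cond)
    }
    chunk <- chunk * 2
  }
}

#' @export
print.dl_steady_state <- function(x, ...) {
  cat(sprintf(
    "<dl_steady_state> %d compartments, t = %g, residual = %.3g\n",
    x$grid$n, x$time, x$residual))
  cat(sprintf("ventral nDl_total = %.4g, dorsal nDl_total = %.4g\n",
              derived_totals(x$state)$nDl_total[1],
              derived_totals(x$state)$nDl_total[x$grid$n]))
  invisible(x)
}

#' @export
as_tibble.dl_steady_state <- function(x, ...) steady_profile(x)

#' Summaries of a converged run
#'
#' `glance()` reports one-row convergence diagnostics; `tidy()` returns
#' the long species-by-position table.
#'
#' @param x A `dl_steady_state`.
#' @param ... Unused.
#' @export
glance.dl_steady_state <- function(x, ...) {
  tibble::tibble(n_compartments = x$grid$n, time = x$time,
                 residual = x$residual, converged = x$converged,
                 dl_grand_total = dl_grand_total(x$state))
}

#' @rdname glance.dl_steady_state
#' @export
tidy.dl_steady_state <- function(x, ...) tidy.dl_state(x$state)

#' Single-compartment algebraic steady state
#'
#' Independent oracle for the solver: in one well-mixed compartment the
#' steady state reduces, via Dorsal and Toll conservation and the fast
#' linear balances of the nuclear and starred species, to two nested
#' scalar root-finding problems (in `DlC` given `cDl0`, then in `cDl0`),
#' solved with [stats::uniroot()]. Implemented for the default
#' structural switches only.
#'
#' @param params A [dl_params()] object (default switches).
#' @param toll_total Total activated Toll in the compartment (>= 0).
#' @return Named numeric vector of the nine steady-state concentrations.
#' @examples
#' s <- single_compartment_steady_state(dl_params(), toll_total = 0)
#' s["nDl0"] / s["cDl0"]  # k3 / k4
#' @export
single_compartment_steady_state <- function(params, toll_total) {
  stopifnot(inherits(params, "dl_params"), toll_total >= 0)
  if (params$synthesis_driver != "cDl0" ||
      params$k12_destination != "cDl0" ||
      params$toll_recycling != "recycled") {
    stop("the algebraic oracle supports the default structural switches only",
         call. = FALSE)
  }
  p <- params
  out <- setNames(numeric(9), dl_species())
  out["T"] <- toll_total
  if (p$Dl_tot == 0) return(out)

  # Closures at steady state:
  #   DlCT = k7 DlC (T0 - DlCT) / (k8 + k9)
  #   Cf   = (k1 cDl0 - k9 DlCT) / k2          (total-Cactus balance)
  #   DlC balance: k5 cDl0 Cf = k6 DlC + k9 DlCT
  #   nDl0 = (k3/k4) cDl0; cDl* = (k9/k11) DlCT; nDl* = (k9/k12) DlCT
  dlct_of <- function(DlC) {
    p$k7 * DlC * toll_total / (p$k8 + p$k9 + p$k7 * DlC)
  }
  dlc_given <- function(cDl0) {
    g <- function(DlC) {
      DlCT <- dlct_of(DlC)
      Cf <- (p$k1 * cDl0 - p$k9 * DlCT) / p$k2
      p$k5 * cDl0 * Cf - p$k6 * DlC - p$k9 * DlCT
    }
    upper <- p$k5 * cDl0 * (p$k1 * cDl0 / p$k2) / p$k6 + 1
    if (g(0) <= 0) return(0)
    stats::uniroot(g, c(0, upper), tol = 1e-15)$root
  }
  conserve <- function(cDl0) {
    DlC <- dlc_given(cDl0)
    DlCT <- dlct_of(DlC)
    cDl0 * (1 + p$k3 / p$k4) + DlC +
      DlCT * (1 + p$k9 / p$k11 + p$k9 / p$k12) - p$Dl_tot
  }
  hi <- p$Dl_tot / (1 + p$k3 / p$k4)
  cDl0 <- stats::uniroot(conserve, c(0, hi), tol = 1e-15)$root
  DlC <- dlc_given(cDl0)
  DlCT <- dlct_of(DlC)
  res <- max(abs(conserve(cDl0)))
  if (!is.finite(res) || res > 1e-8 * max(1, p$Dl_tot)) {
    stop("single-compartment root finding did not converge (residual ",
         signif(res, 3), ")", call. = FALSE)
  }
  out["cDl0"] <- cDl0
  out["nDl0"] <- p$k3 / p$k4 * cDl0
  out["DlC"] <- DlC
  out["DlCT"] <- DlCT
  out["T"] <- toll_total - DlCT
  out["Cub"] <- p$k9 * DlCT / p$k10
  out["cDlstar"] <- p$k9 * DlCT / p$k11
  out["nDlstar"] <- p$k9 * DlCT / p$k12
  out["Cf"] <- (p$k1 * cDl0 - p$k9 * DlCT) / p$k2
  out
}
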