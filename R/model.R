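#' Gaussian activated-Toll initial profile
#'
#' Activated Toll is ventrally peaked: its concentration along the half
#' axis is a Gaussian with mean pinned at the ventral midline (x = 0),
#' amplitude `toll_amp` and standard deviation `toll_sigma`, evaluated
#' at compartment centers.
#'
#' @param grid A [dl_grid()].
#' @param toll_amp Peak concentration (>= 0; 0 gives a Toll-null embryo).
#' @param toll_sigma Gaussian standard deviation in half-axis units
#'   (> 0).
#' @return Numeric vector of length `grid$n`, maximal at the
#'   ventral-most compartment.
#' @examples
#' toll_profile(dl_grid(), 8.54, 0.1995)[1]
#' @export
toll_profile <- function(grid, toll_amp, toll_sigma) {
  stopifnot(inherits(grid, "dl_grid"))
  if (!is.finite(toll_sigma) || toll_sigma <= 0) {
    stop("toll_sigma must be strictly positive", call. = FALSE)
  }
  if (!is.finite(toll_amp) || toll_amp < 0) {
    stop("toll_amp must be non-negative", call. = FALSE)
  }
  toll_amp * exp(-grid$positions^2 / (2 * toll_sigma^2))
}

#' Per-compartment species state
#'
#' A `dl_state` couples a concentration matrix (compartments in rows,
#' the nine species of [dl_species()] in columns) to its grid.
#'
#' @param conc Numeric matrix `grid$n` x 9 with column names
#'   `dl_species()`.
#' @param grid A [dl_grid()].
#' @return An object of class `dl_state`.
#' @export
dl_state <- function(conc, grid) {
  stopifnot(inherits(grid, "dl_grid"))
  conc <- as.matrix(conc)
  if (nrow(conc) != grid$n || ncol(conc) != 9) {
    stop("state must be an n_compartments x 9 matrix", call. = FALSE)
  }
  if (is.null(colnames(conc))) colnames(conc) <- dl_species()
  if (!identical(colnames(conc), dl_species())) {
    conc <- conc[, dl_species(), drop = FALSE]
  }
  structure(list(conc = conc, grid = grid), class = "dl_state")
}

#' @export
print.dl_state <- function(x, ...) {
  cat(sprintf("<dl_state> 9 species x %d compartments\n", x$grid$n))
  print(utils::head(tibble::as_tibble(x), 4))
  invisible(x)
}

#' @export
as_tibble.dl_state <- function(x, ...) {
  tibble::as_tibble(cbind(position = x$grid$positions,
                          as.data.frame(x$conc)))
}

#' @export
tidy.dl_state <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"position",
                      names_to = "species", values_to = "concentration")
}

#' Initial condition of a simulation
#'
#' All Dorsal starts as free cytoplasmic dimer at uniform concentration
#' `Dl_tot`; activated Toll follows its Gaussian profile; the remaining
#' seven species start at zero.
#'
#' @param params A [dl_params()] object.
#' @param grid A [dl_grid()].
#' @return A [dl_state()].
#' @examples
#' s0 <- initial_state(dl_params(), dl_grid())
#' unique(s0$conc[, "cDl0"])
#' @export
initial_state <- function(params, grid = dl_grid()) {
  stopifnot(inherits(params, "dl_params"))
  conc <- matrix(0, nrow = grid$n, ncol = 9,
                 dimnames = list(NULL, dl_species()))
  conc[, "cDl0"] <- params$Dl_tot
  conc[, "T"] <- toll_profile(grid, params$toll_amp, params$toll_sigma)
  dl_state(conc, grid)
}

#' Mass-action net reaction rates in one compartment
#'
#' Evaluates the net contribution of the twelve reactions to each
#' species in a single well-mixed compartment (no diffusion). The
#' network is: Dorsal-driven Cactus synthesis (k1) and Toll-independent
#' Cactus turnover (k2); reversible direct nuclear flow of free Dorsal
#' (k3/k4); reversible Dorsal-Cactus trimer formation (k5/k6);
#' reversible recruitment of the trimer by activated Toll (k7/k8); the
#' irreversible signalling step releasing phosphorylated Dorsal,
#' ubiquitinated Cactus and the receptor (k9); proteasomal degradation
#' of ubiquitinated Cactus (k10); nuclear import of phosphorylated
#' Dorsal (k11); and its nuclear export (k12).
#'
#' @param conc Named numeric vector of the nine species concentrations
#'   (names as [dl_species()]), all non-negative.
#' @param params A [dl_params()] object.
#' @return Named numeric vector of net rates, one per species.
#' @examples
#' conc <- setNames(numeric(9), dl_species())
#' conc[c("cDl0", "Cf")] <- 1
#' reaction_rates(conc, dl_params())["DlC"]  # = k5
#' @export
reaction_rates <- function(conc, params) {
  stopifnot(inherits(params, "dl_params"))
  conc <- conc[dl_species()]
  if (anyNA(conc)) stop("concentrations must be named by dl_species()",
                        call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative",
                          call. = FALSE)
  m <- matrix(conc, nrow = 1, dimnames = list(NULL, dl_species()))
  reaction_rates_matrix(m, params)[1, ]
}

# Vectorized over compartments: `conc` is an n x 9 matrix.
reaction_rates_matrix <- function(conc, p) {
  cDl0 <- conc[, "cDl0"]; nDl0 <- conc[, "nDl0"]; Cf <- conc[, "Cf"]
  DlC <- conc[, "DlC"];   Tf <- conc[, "T"];      DlCT <- conc[, "DlCT"]
  Cub <- conc[, "Cub"];   cDls <- conc[, "cDlstar"]; nDls <- conc[, "nDlstar"]

  r3 <- p$k3 * cDl0; r4 <- p$k4 * nDl0
  r5 <- p$k5 * cDl0 * Cf; r6 <- p$k6 * DlC
  r7 <- p$k7 * DlC * Tf; r8 <- p$k8 * DlCT; r9 <- p$k9 * DlCT
  r10 <- p$k10 * Cub; r11 <- p$k11 * cDls; r12 <- p$k12 * nDls
  syn <- if (p$synthesis_driver == "cDl_total") {
    p$k1 * (cDl0 + cDls + DlC + DlCT)
  } else {
    p$k1 * cDl0
  }

  d <- cbind(
    cDl0   = -r3 + r4 - r5 + r6,
    nDl0   = r3 - r4,
    Cf     = syn - p$k2 * Cf - r5 + r6,
    DlC    = r5 - r6 - r7 + r8,
    T      = -r7 + r8,
    DlCT   = r7 - r8 - r9,
    Cub    = r9 - r10,
    cDlstar = r9 - r11,
    nDlstar = r11 - r12
  )
  if (p$toll_recycling == "recycled") d[, "T"] <- d[, "T"] + r9
  if (p$k12_destination == "cDl0") {
    d[, "cDl0"] <- d[, "cDl0"] + r12
  } else {
    d[, "cDlstar"] <- d[, "cDlstar"] + r12
  }
  d
}

#' Time derivative of the full compartmental state
#'
#' Reference (pure-R) right-hand side of the method-of-lines system:
#' mass-action reactions in every compartment plus Fickian diffusion for
#' the three diffusing species (`cDl0`, `Cf`, `DlC`) with no-flux
#' boundaries at both midlines. All other species are immobile. The
#' steady-state integrator uses a compiled translation of this function;
#' the two are tested for agreement.
#'
#' @param state A [dl_state()].
#' @param params A [dl_params()] object.
#' @param grid A [dl_grid()]; must match the state's grid.
#' @return A [dl_state()] holding d(concentration)/dt.
#' @export
model_rhs <- function(state, params, grid = state$grid) {
  stopifnot(inherits(state, "dl_state"), inherits(params, "dl_params"))
  if (!identical(grid$n, state$grid$n)) {
    stop("grid does not match the state's grid", call. = FALSE)
  }
  d <- reaction_rates_matrix(state$conc, params)
  if (grid$n > 1) {
    for (sp in c("cDl0", "Cf", "DlC")) {
      D <- switch(sp, cDl0 = params$D_Dl, Cf = params$D_C, DlC = params$D_DlC)
      d[, sp] <- d[, sp] + D * laplacian_noflux(state$conc[, sp], grid$dx)
    }
  }
  dl_state(d, grid)
}

#' Derived totals and conservation readouts
#'
#' Per-compartment sums over species groups: total nuclear Dorsal
#' (`nDl_total = nDl0 + nDlstar`, the observable gradient), total
#' cytoplasmic Dorsal (`cDl_total = cDl0 + cDlstar + DlC + DlCT`) and
#' total Cactus (`C_total = Cf + Cub + DlC + DlCT`).
#'
#' @param state A [dl_state()].
#' @return A tibble with columns `position`, `nDl_total`, `cDl_total`
#'   and `C_total`.
#' @seealso [dl_grand_total()] for the conserved whole-embryo Dorsal sum.
#' @export
derived_totals <- function(state) {
  stopifnot(inherits(state, "dl_state"))
  m <- state$conc
  tibble::tibble(
    position = state$grid$positions,
    nDl_total = m[, "nDl0"] + m[, "nDlstar"],
    cDl_total = m[, "cDl0"] + m[, "cDlstar"] + m[, "DlC"] + m[, "DlCT"],
    C_total = m[, "Cf"] + m[, "Cub"] + m[, "DlC"] + m[, "DlCT"]
  )
}

#' @rdname derived_totals
#' @return `dl_grand_total()` returns the scalar sum over compartments of
#'   all Dorsal-containing species (each of `DlC` and `DlCT` carries one
#'   Dorsal dimer). The model conserves this quantity exactly.
#' @export
dl_grand_total <- function(state) {
  stopifnot(inherits(state, "dl_state"))
  m <- state$conc
  sum(m[, "cDl0"] + m[, "nDl0"] + m[, "DlC"] + m[, "DlCT"] +
        m[, "cDlstar"] + m[, "nDlstar"])
}
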