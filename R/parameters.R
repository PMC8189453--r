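#' Model species names
#'
#' The nine chemical species of the Dorsal/Cactus/Toll network, in the
#' canonical order used throughout the package: free cytoplasmic Dorsal
#' dimer (`cDl0`), nuclear Dorsal imported by direct flow (`nDl0`), free
#' Cactus (`Cf`), the Dorsal-Cactus trimer (`DlC`), free activated Toll
#' (`T`), the Toll-bound signalling complex (`DlCT`),
#' phospho/ubiquitinated Cactus (`Cub`), Toll-phosphorylated cytoplasmic
#' Dorsal (`cDlstar`) and Toll-induced nuclear Dorsal (`nDlstar`).
#'
#' @return Character vector of length 9.
#' @export
dl_species <- function() {
  c("cDl0", "nDl0", "Cf", "DlC", "T", "DlCT", "Cub", "cDlstar", "nDlstar")
}

#' Names of the calibrated dimensionless parameters
#'
#' The 18 calibrated quantities: kinetic constants `k1`--`k12` (per
#' characteristic time; `k5` and `k7` are bimolecular), diffusivities
#' `D_Dl`, `D_C`, `D_DlC` (half-embryo lengths squared per characteristic
#' time), the uniform initial cytoplasmic Dorsal-dimer concentration
#' `Dl_tot`, and the activated-Toll profile peak `toll_amp` and Gaussian
#' width `toll_sigma` (half-axis units).
#'
#' @return Character vector of length 18.
#' @export
dl_param_names <- function() {
  c(paste0("k", 1:12), "D_Dl", "D_C", "D_DlC",
    "Dl_tot", "toll_amp", "toll_sigma")
}

#' Dimensionless model parameters
#'
#' Constructs the parameter set of the Dorsal nuclear-gradient network.
#' Defaults are the calibrated wild-type values; all concentrations are
#' in units of the wild-type ventral nuclear-Dorsal concentration, all
#' lengths in half-embryo lengths, and all times in the model's
#' characteristic time (see [time_scale()] for its dimensional value).
#'
#' Three structural switches expose points where the network wiring
#' admits more than one defensible closure:
#' \describe{
#'   \item{`synthesis_driver`}{which Dorsal pool drives Cactus synthesis
#'     (`"cDl0"`, the default: free cytoplasmic Dorsal; or `"cDl_total"`:
#'     all cytoplasmic Dorsal species).}
#'   \item{`k12_destination`}{the pool into which nuclear-exported
#'     Toll-route Dorsal returns (`"cDl0"`, the default, or `"cDlstar"`).}
#'   \item{`toll_recycling`}{whether the Toll receptor freed by the
#'     signalling step returns to the active pool (`"recycled"`, the
#'     default, which conserves Toll per compartment) or is consumed
#'     (`"consumed"`).}
#' }
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8,k9,k10,k11,k12 Kinetic constants.
#' @param D_Dl,D_C,D_DlC Diffusivities of free cytoplasmic Dorsal, free
#'   Cactus and the Dorsal-Cactus trimer. All other species do not
#'   diffuse.
#' @param Dl_tot Total Dorsal-dimer concentration (uniform initial
#'   cytoplasmic value).
#' @param toll_amp Activated-Toll peak concentration (may be 0 for
#'   Toll-null scenarios).
#' @param toll_sigma Standard deviation of the Gaussian Toll activation
#'   profile, in half-axis units.
#' @param synthesis_driver,k12_destination,toll_recycling Structural
#'   switches, see Details.
#' @return An object of class `dl_params`: a named list with the 18
#'   numeric parameters plus the three switches.
#' @examples
#' p <- dl_params()
#' p$k11 / p$k12   # Toll-route import/export ratio
#' dl_params(Dl_tot = 0.4605)  # the dl6/+ genotype
#' @export
dl_params <- function(k1 = 0.584, k2 = 0.0610, k3 = 0.0043, k4 = 0.0022,
                      k5 = 877, k6 = 7510, k7 = 0.113, k8 = 0.0023,
                      k9 = 0.0036, k10 = 427, k11 = 1.20, k12 = 0.0022,
                      D_Dl = 91, D_C = 415, D_DlC = 3.39e-5,
                      Dl_tot = 0.525, toll_amp = 8.54, toll_sigma = 0.1995,
                      synthesis_driver = c("cDl0", "cDl_total"),
                      k12_destination = c("cDl0", "cDlstar"),
                      toll_recycling = c("recycled", "consumed")) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
            k7 = k7, k8 = k8, k9 = k9, k10 = k10, k11 = k11, k12 = k12,
            D_Dl = D_Dl, D_C = D_C, D_DlC = D_DlC,
            Dl_tot = Dl_tot, toll_amp = toll_amp, toll_sigma = toll_sigma,
            synthesis_driver = match.arg(synthesis_driver),
            k12_destination = match.arg(k12_destination),
            toll_recycling = match.arg(toll_recycling))
  validate_dl_params(p)
  structure(p, class = "dl_params")
}

validate_dl_params <- function(p) {
  num <- dl_param_names()
  vals <- unlist(p[num])
  if (!all(is.finite(vals))) {
    stop("all model parameters must be finite numbers", call. = FALSE)
  }
  must_pos <- setdiff(num, "toll_amp")
  if (any(vals[must_pos] <= 0)) {
    bad <- must_pos[vals[must_pos] <= 0]
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$toll_amp < 0) {
    stop("toll_amp must be non-negative", call. = FALSE)
  }
  if (p$toll_sigma > 1) {
    warning("toll_sigma > 1 half-axis unit: the Toll profile is nearly ",
            "flat over the physical domain", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.dl_params <- function(x, ...) {
  cat("<dl_params> dimensionless Dorsal-gradient model parameters\n")
  vals <- unlist(x[dl_param_names()])
  print(signif(vals, 4))
  cat(sprintf("switches: synthesis_driver=%s, k12_destination=%s, toll_recycling=%s\n",
              x$synthesis_driver, x$k12_destination, x$toll_recycling))
  invisible(x)
}

#' @export
as.data.frame.dl_params <- function(x, ...) {
  as.data.frame(tidy.dl_params(x))
}

#' Tidy a parameter set into a two-column tibble
#'
#' @param x A [dl_params()] object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy.dl_params <- function(x, ...) {
  tibble::tibble(parameter = dl_param_names(),
                 value = unname(unlist(x[dl_param_names()])))
}

#' Read or write a parameter configuration file
#'
#' Flat key-value YAML or JSON files holding any subset of the 18
#' parameter names plus the structural switches and, optionally,
#' `n_compartments`. Unspecified parameters take their wild-type
#' defaults.
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return `read_params()` returns a [dl_params()] object (with an
#'   `n_compartments` attribute when the file sets one);
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c(dl_param_names(), "synthesis_driver", "k12_destination",
             "toll_recycling", "n_compartments")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_comp <- raw$n_compartments
  raw$n_compartments <- NULL
  p <- do.call(dl_params, raw)
  if (!is.null(n_comp)) attr(p, "n_compartments") <- as.integer(n_comp)
  p
}

#' @param params A [dl_params()] object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "dl_params"))
  out <- c(as.list(unlist(params[dl_param_names()])),
           params[c("synthesis_driver", "k12_destination", "toll_recycling")])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Spatial discretization of the half embryo
#'
#' The model domain is the ventral-to-dorsal half of a transverse embryo
#' cross-section, of unit length, split into equal well-mixed
#' nucleo-cytoplasmic compartments. Position 0 is the ventral midline,
#' position 1 the dorsal midline; concentrations are evaluated at
#' compartment centers.
#'
#' @param n_compartments Number of compartments (default 50, so each
#'   compartment is 1/50 of the half axis).
#' @return An object of class `dl_grid`: list with `n`, `dx` and the
#'   compartment-center `positions`.
#' @examples
#' g <- dl_grid()
#' head(g$positions)
#' @export
dl_grid <- function(n_compartments = 50) {
  n <- as.integer(n_compartments)
  if (is.na(n) || n < 1) stop("n_compartments must be a positive integer",
                              call. = FALSE)
  dx <- 1 / n
  structure(list(n = n, dx = dx, positions = (seq_len(n) - 0.5) * dx),
            class = "dl_grid")
}

#' @export
print.dl_grid <- function(x, ...) {
  cat(sprintf("<dl_grid> %d compartments of width %.4g on [0, 1]\n",
              x$n, x$dx))
  invisible(x)
}
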