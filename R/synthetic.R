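#' Model-based synthetic gradient data
#'
#' Emulates the statistical structure of quantified embryo gradients:
#' the steady-state nuclear-Dorsal profile of a known ("truth")
#' parameter set is measured in `n_embryos` noisy replicates per
#' position, and the per-position mean and standard error are returned
#' — the same mean +/- s.e.m. layout the calibration reader consumes.
#' Noise is additive homoscedastic Gaussian by default; the
#' heteroscedastic option scales the noise s.d. with the local mean.
#'
#' @param truth A [dl_params()] object used as ground truth.
#' @param grid,config Grid and solver configuration for the truth run.
#' @param n_embryos Replicates per position (default 10).
#' @param noise_sd Per-measurement noise standard deviation in
#'   dimensionless nuclear-Dorsal units (default 0.05).
#' @param seed RNG seed (`NULL` = leave RNG alone).
#' @param heteroscedastic If `TRUE`, each measurement's s.d. is
#'   `noise_sd * mean` at that position.
#' @param jitter_positions If `TRUE`, positions are uniformly jittered
#'   within each compartment to emulate nucleus-indexed sampling.
#' @return Tibble with columns `position`, `nDl` (mean), `sem`;
#'   attributes `truth` (the parameter set) and `profile` (the
#'   noise-free simulated profile).
#' @examples
#' \donttest{
#' d <- simulate_gradient_data(noise_sd = 0.05, seed = 1)
#' head(d)
#' }
#' @export
simulate_gradient_data <- function(truth = dl_params(), grid = dl_grid(),
                                   config = solver_config(),
                                   n_embryos = 10, noise_sd = 0.05,
                                   seed = NULL, heteroscedastic = FALSE,
                                   jitter_positions = FALSE) {
  stopifnot(n_embryos >= 1, noise_sd >= 0, grid$n >= 3)
  ss <- steady_state(truth, grid, config)
  clean <- nDl_profile(ss)
  if (!is.null(seed)) set.seed(seed)
  pos <- clean$position
  if (jitter_positions) {
    pos <- pos + stats::runif(grid$n, -grid$dx / 2, grid$dx / 2)
    pos <- sort(pos)
  }
  mu <- stats::approx(clean$position, clean$nDl, xout = pos, rule = 2)$y
  sds <- if (heteroscedastic) noise_sd * mu else rep(noise_sd, length(mu))
  reps <- matrix(stats::rnorm(length(mu) * n_embryos, mean = mu,
                              sd = rep(sds, n_embryos)),
                 nrow = length(mu))
  out <- tibble::tibble(
    position = pos,
    nDl = rowMeans(reps),
    sem = apply(reps, 1, stats::sd) / sqrt(n_embryos))
  if (n_embryos == 1) out$sem <- rep(0, length(mu))
  attr(out, "truth") <- truth
  attr(out, "profile") <- clean
  out
}

#' Phenomenological synthetic gradient
#'
#' Gaussian-plus-basal gradient shape — a ventrally peaked decreasing
#' curve over a uniform dorsal baseline — sampled with the same
#' replicate-noise scheme as [simulate_gradient_data()], without
#' running the mechanistic model.
#'
#' @param n_positions Number of positions on \[0, 1\] (compartment
#'   centers).
#' @param amplitude,basal,width Shape parameters: mean profile is
#'   `basal + amplitude * exp(-x^2 / (2 width^2))`.
#' @param noise_sd,n_embryos,seed As in [simulate_gradient_data()].
#' @param normalize If `TRUE`, scale so the ventral-most mean is
#'   exactly 1.
#' @return Tibble with columns `position`, `nDl`, `sem`.
#' @examples
#' simulate_phenom_gradient(5, noise_sd = 0)
#' @export
simulate_phenom_gradient <- function(n_positions = 50, amplitude = 0.8,
                                     basal = 0.2, width = 0.2,
                                     noise_sd = 0, n_embryos = 10,
                                     seed = NULL, normalize = FALSE) {
  stopifnot(n_positions >= 3, amplitude >= 0, basal >= 0, width > 0,
            noise_sd >= 0, n_embryos >= 1)
  x <- (seq_len(n_positions) - 0.5) / n_positions
  mu <- basal + amplitude * exp(-x^2 / (2 * width^2))
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(stats::rnorm(n_positions * n_embryos, mean = mu,
                              sd = noise_sd), nrow = n_positions)
  out <- tibble::tibble(position = x, nDl = rowMeans(reps),
                        sem = apply(reps, 1, stats::sd) / sqrt(n_embryos))
  if (n_embryos == 1 || noise_sd == 0) out$sem <- rep(0, n_positions)
  if (normalize) {
    f <- out$nDl[1]
    if (f <= 0) stop("cannot normalize: ventral-most mean is not positive",
                     call. = FALSE)
    out$nDl <- out$nDl / f
    out$sem <- out$sem / f
  }
  out
}

#' Normalize a set of gradients to a control
#'
#' Divides every profile (means and s.e.m.) by the control's
#' ventral-most mean, mirroring the co-processing of mutant and
#' control embryos: mutants scale by the same factor as their paired
#' control, so the control's ventral value becomes 1 and mutant levels
#' stay comparable across genotypes. Idempotent once applied.
#'
#' @param profiles Named list of gradient tibbles (columns `position`,
#'   `nDl`, optional `sem`).
#' @param control Name of the control profile in `profiles`.
#' @return The list with every profile rescaled.
#' @examples
#' ctl <- tibble::tibble(position = c(.1, .5), nDl = c(2, 1))
#' mut <- tibble::tibble(position = c(.1, .5), nDl = c(1, .5))
#' normalize_to_control(list(wt = ctl, mut = mut), "wt")$mut$nDl
#' @export
normalize_to_control <- function(profiles, control) {
  stopifnot(is.list(profiles), control %in% names(profiles))
  f <- profiles[[control]]$nDl[1]
  if (!is.finite(f) || f <= 0) {
    stop("control ventral-most value must be positive", call. = FALSE)
  }
  lapply(profiles, function(p) {
    p$nDl <- p$nDl / f
    if ("sem" %in% names(p)) p$sem <- p$sem / f
    p
  })
}
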