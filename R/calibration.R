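#' Quadratic loss between a simulated and an experimental gradient
#'
#' Sum of squared differences between the model nuclear-Dorsal profile,
#' linearly interpolated onto the experimental positions, and the
#' experimental means. Experimental data are expected on the
#' control-normalized scale (ventral-most wild-type value = 1), the same
#' scale the calibrated model produces.
#'
#' @param model_profile Tibble with columns `position`, `nDl`.
#' @param exp_profile Tibble with columns `position`, `nDl` (at least
#'   one row).
#' @return Non-negative scalar; 0 iff the profiles agree at every
#'   experimental position.
#' @examples
#' p <- tibble::tibble(position = c(0.1, 0.5, 0.9), nDl = c(1, .5, .2))
#' quadratic_loss(p, p)
#' @export
quadratic_loss <- function(model_profile, exp_profile) {
  stopifnot(is.data.frame(model_profile), is.data.frame(exp_profile),
            all(c("position", "nDl") %in% names(model_profile)),
            all(c("position", "nDl") %in% names(exp_profile)))
  if (nrow(exp_profile) == 0) {
    stop("experimental profile is empty", call. = FALSE)
  }
  pred <- stats::approx(model_profile$position, model_profile$nDl,
                        xout = exp_profile$position, rule = 2)$y
  sum((pred - exp_profile$nDl)^2)
}

#' Default calibration bounds
#'
#' Per-parameter search intervals for the genetic algorithm: kinetic
#' constants and diffusivities span four log-decades centred on the
#' wild-type values (searched in log space); the three profile-level
#' parameters use linear intervals wide enough to contain any plausible
#' embryo (`Dl_tot` in \[0, 1\], `toll_amp` in \[0, 20\], `toll_sigma`
#' in \[0.05, 0.5\]).
#'
#' @param center A [dl_params()] object the log intervals are centred
#'   on.
#' @param decades Half-width of the log intervals, in decades.
#' @return Tibble with columns `parameter`, `lo`, `hi`, `scale`
#'   (`"log"` or `"linear"`).
#' @export
ga_bounds <- function(center = dl_params(), decades = 2) {
  logged <- c(paste0("k", 1:12), "D_Dl", "D_C", "D_DlC")
  ctr <- unlist(center[logged])
  tibble::tibble(
    parameter = dl_param_names(),
    lo = c(ctr * 10^-decades, 0, 0, 0.05),
    hi = c(ctr * 10^decades, 1, 20, 0.5),
    scale = c(rep("log", length(logged)), rep("linear", 3))
  )
}

#' Genetic-algorithm configuration
#'
#' Binary-coded genetic algorithm: each of the 18 parameters occupies
#' `bits_per_parameter` bits of the genome, decoded affinely onto its
#' bound interval (in log space where flagged). Selection is by
#' k-tournament, recombination by uniform bit-wise crossover, variation
#' by bit-flip mutation; the best individual is always carried over
#' (elitism), and an optional epidemic restart re-randomizes all but
#' the top `epidemic_survivors` individuals after
#' `epidemic_stagnation` generations without improvement.
#'
#' @param population_size,generations GA scale.
#' @param bits_per_parameter Bits per parameter slice.
#' @param bounds Bounds tibble as from [ga_bounds()].
#' @param tournament_k Tournament size (>= 2).
#' @param crossover_rate Probability that a pair recombines.
#' @param mutation_rate Per-bit flip probability; default `NULL` means
#'   1 / genome length.
#' @param epidemic Logical: enable the epidemic restart.
#' @param epidemic_stagnation,epidemic_survivors Epidemic trigger and
#'   number of elites kept.
#' @param penalty_cost Cost assigned to individuals whose simulation
#'   fails to converge.
#' @param seed RNG seed for a reproducible run (`NULL` = leave RNG
#'   alone).
#' @param solver [solver_config()] used for the per-individual runs;
#'   the default trades residual depth for speed, which is ample for
#'   ranking individuals by a loss of order 1e-3 or more.
#' @return An object of class `dl_ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 200,
                      bits_per_parameter = 16, bounds = ga_bounds(),
                      tournament_k = 3, crossover_rate = 0.9,
                      mutation_rate = NULL, epidemic = TRUE,
                      epidemic_stagnation = 25, epidemic_survivors = 5,
                      penalty_cost = 1e6, seed = NULL,
                      solver = solver_config(rel_tol = 1e-6,
                                             abs_tol = 1e-9,
                                             steady_tol = 1e-7,
                                             t_max = 1e5)) {
  stopifnot(population_size >= 2, generations >= 1,
            bits_per_parameter >= 1, tournament_k >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            nrow(bounds) == 18, all(bounds$lo < bounds$hi),
            all(bounds$lo[bounds$scale == "log"] > 0))
  genome_length <- 18L * as.integer(bits_per_parameter)
  if (is.null(mutation_rate)) mutation_rate <- 1 / genome_length
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 bits_per_parameter = as.integer(bits_per_parameter),
                 genome_length = genome_length,
                 bounds = bounds[match(dl_param_names(), bounds$parameter), ],
                 tournament_k = as.integer(tournament_k),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 epidemic = isTRUE(epidemic),
                 epidemic_stagnation = as.integer(epidemic_stagnation),
                 epidemic_survivors = as.integer(epidemic_survivors),
                 penalty_cost = penalty_cost, seed = seed,
                 solver = solver),
            class = "dl_ga_config")
}

#' Decode a binary genome into model parameters
#'
#' Each parameter's bit slice is read as an unsigned integer
#' (most-significant bit first) and mapped affinely onto \[lo, hi\] —
#' in log10 space for log-scaled bounds — so the all-zero slice decodes
#' to `lo` and the all-one slice to `hi`.
#'
#' @param genome Integer/logical vector of 0/1 of length
#'   `18 * bits_per_parameter`.
#' @param config A [ga_config()].
#' @return A [dl_params()] object.
#' @export
decode_genome <- function(genome, config) {
  stopifnot(inherits(config, "dl_ga_config"))
  if (length(genome) != config$genome_length) {
    stop("genome length ", length(genome), " does not match config (",
         config$genome_length, ")", call. = FALSE)
  }
  b <- config$bits_per_parameter
  pows <- 2^((b - 1):0)
  denom <- 2^b - 1
  vals <- numeric(18)
  for (i in seq_len(18)) {
    slice <- genome[((i - 1) * b + 1):(i * b)]
    frac <- sum(slice * pows) / denom
    lo <- config$bounds$lo[i]; hi <- config$bounds$hi[i]
    vals[i] <- if (config$bounds$scale[i] == "log") {
      10^(log10(lo) + frac * (log10(hi) - log10(lo)))
    } else {
      lo + frac * (hi - lo)
    }
  }
  names(vals) <- dl_param_names()
  # Build directly (not via dl_params()) so that boundary genomes decoding
  # to a zero-valued parameter (e.g. Dl_tot at a linear lower bound of 0)
  # still decode; such parameter sets are scored, not rejected.
  structure(c(as.list(vals),
              list(synthesis_driver = "cDl0", k12_destination = "cDl0",
                   toll_recycling = "recycled")),
            class = "dl_params")
}

ga_genome_key <- function(genome) paste(as.integer(genome), collapse = "")

#' Calibrate the model against a gradient profile
#'
#' Generational genetic-algorithm loop: evaluate every individual
#' (steady-state simulation + [quadratic_loss()]), select parents by
#' k-tournament, recombine by uniform bit-wise crossover, mutate by
#' bit-flip, carry the best individual over unchanged, and apply the
#' epidemic restart on stagnation. Individuals whose simulation fails
#' receive `penalty_cost` rather than aborting the run. Identical seeds
#' give identical runs. Repeated genomes are evaluated once (cached).
#'
#' @param exp_profile Gradient tibble with columns `position`, `nDl`.
#' @param config A [ga_config()].
#' @param base A [dl_params()] supplying the structural switches (the
#'   18 numeric values come from the genome).
#' @param grid A [dl_grid()].
#' @param initial_population Optional 0/1 matrix (`population_size` x
#'   genome length) seeding generation zero; by default the population
#'   is drawn uniformly at random.
#' @return An object of class `dl_ga_fit`: list with `best` (genome,
#'   decoded `params`, `cost`), `population` (tibble of the final
#'   generation: 18 parameter columns + `cost`), `history` (tibble
#'   `generation`, `best_cost`, `mean_cost`), `evaluations` and the
#'   `config`.
#' @export
ga_evolve <- function(exp_profile, config = ga_config(),
                      base = dl_params(), grid = dl_grid(),
                      initial_population = NULL) {
  stopifnot(inherits(config, "dl_ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length
  np <- config$population_size
  cache <- new.env(parent = emptyenv())
  evaluations <- 0L

  eval_genome <- function(genome) {
    key <- ga_genome_key(genome)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cost <- tryCatch({
      params <- decode_genome(genome, config)
      params$synthesis_driver <- base$synthesis_driver
      params$k12_destination <- base$k12_destination
      params$toll_recycling <- base$toll_recycling
      ss <- steady_state(params, grid, config$solver)
      quadratic_loss(nDl_profile(ss), exp_profile)
    }, error = function(e) config$penalty_cost)
    if (!is.finite(cost)) cost <- config$penalty_cost
    evaluations <<- evaluations + 1L
    cache[[key]] <- cost
    cost
  }

  pop <- if (is.null(initial_population)) {
    matrix(sample(0:1, np * L, replace = TRUE), nrow = np)
  } else {
    stopifnot(is.matrix(initial_population),
              nrow(initial_population) == np,
              ncol(initial_population) == L)
    initial_population
  }
  costs <- apply(pop, 1, eval_genome)
  history <- tibble::tibble(generation = integer(), best_cost = double(),
                            mean_cost = double())
  stagnation <- 0L
  best_so_far <- Inf

  tournament <- function() {
    idx <- sample.int(np, config$tournament_k, replace = FALSE)
    idx[which.min(costs[idx])]
  }

  for (gen in seq_len(config$generations)) {
    gen_best <- min(costs)
    history <- dplyr::bind_rows(history, tibble::tibble(
      generation = gen, best_cost = gen_best, mean_cost = mean(costs)))
    if (gen_best < best_so_far - 1e-15) {
      best_so_far <- gen_best
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }

    if (config$epidemic && stagnation >= config$epidemic_stagnation) {
      keep <- order(costs)[seq_len(min(config$epidemic_survivors, np))]
      newpop <- matrix(sample(0:1, np * L, replace = TRUE), nrow = np)
      newpop[seq_along(keep), ] <- pop[keep, , drop = FALSE]
      pop <- newpop
      costs <- apply(pop, 1, eval_genome)
      stagnation <- 0L
      next
    }

    elite_idx <- which.min(costs)
    newpop <- matrix(0L, nrow = np, ncol = L)
    newpop[1, ] <- pop[elite_idx, ]
    for (i in 2:np) {
      p1 <- pop[tournament(), ]
      child <- if (stats::runif(1) < config$crossover_rate) {
        p2 <- pop[tournament(), ]
        mask <- stats::runif(L) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      flip <- stats::runif(L) < config$mutation_rate
      child[flip] <- 1L - child[flip]
      newpop[i, ] <- child
    }
    pop <- newpop
    costs <- apply(pop, 1, eval_genome)
  }

  best_idx <- which.min(costs)
  best_params <- decode_genome(pop[best_idx, ], config)
  pop_tbl <- tibble::as_tibble(as.data.frame(t(apply(pop, 1, function(g) {
    unlist(decode_genome(g, config)[dl_param_names()])
  }))))
  pop_tbl$cost <- costs
  structure(list(
    best = list(genome = pop[best_idx, ], params = best_params,
                cost = costs[best_idx]),
    population = pop_tbl, history = history,
    evaluations = evaluations, config = config),
    class = "dl_ga_fit")
}

#' @export
print.dl_ga_fit <- function(x, ...) {
  cat(sprintf(
    "<dl_ga_fit> %d generations, pop %d, %d evaluations, best cost %.4g\n",
    max(x$history$generation), x$config$population_size,
    x$evaluations, x$best$cost))
  invisible(x)
}

#' Tidy and glance methods for a calibration fit
#'
#' `tidy()` returns one row per parameter with the best decoded value
#' and its search bounds; `glance()` a one-row run summary.
#'
#' @param x A `dl_ga_fit`.
#' @param ... Unused.
#' @export
tidy.dl_ga_fit <- function(x, ...) {
  dplyr::mutate(x$config$bounds,
                estimate = unname(unlist(x$best$params[dl_param_names()])),
                .after = "parameter")
}

#' @rdname tidy.dl_ga_fit
#' @export
glance.dl_ga_fit <- function(x, ...) {
  tibble::tibble(best_cost = x$best$cost,
                 generations = max(x$history$generation),
                 population_size = x$config$population_size,
                 evaluations = x$evaluations,
                 final_mean_cost = x$history$mean_cost[nrow(x$history)])
}

#' Select the elite of an evaluated population
#'
#' @param population A `dl_ga_fit` or a tibble with a `cost` column.
#' @param threshold Cost cutoff (individuals with `cost <= threshold`
#'   are kept).
#' @return The selected rows sorted by increasing cost (possibly
#'   empty).
#' @examples
#' elite_selection(tibble::tibble(cost = c(0.01, 0.07, 0.05)), 0.069)
#' @export
elite_selection <- function(population, threshold) {
  if (inherits(population, "dl_ga_fit")) population <- population$population
  stopifnot(is.data.frame(population), "cost" %in% names(population))
  if (anyNA(population$cost)) stop("all costs must be set", call. = FALSE)
  out <- population[population$cost <= threshold, , drop = FALSE]
  tibble::as_tibble(out[order(out$cost), , drop = FALSE])
}

#' Per-parameter histograms and spread of an elite population
#'
#' Bins each parameter over the elite individuals — on a log10 axis for
#' kinetic constants and diffusivities — and summarizes the spread by
#' the interquartile range, flagging parameters whose relative spread
#' (IQR / |median|) falls below `narrow_ratio` as tightly constrained
#' by the data.
#'
#' @param elite Tibble of elite individuals (18 parameter columns, as
#'   from [elite_selection()]); must be non-empty.
#' @param bins Number of histogram bins.
#' @param narrow_ratio Threshold on IQR / |median| below which a
#'   parameter is flagged `narrow`.
#' @return List with `histograms` (tibble: `parameter`, `bin_lo`,
#'   `bin_hi`, `bin_mid`, `count`, `log_scale`) and `summary` (tibble:
#'   `parameter`, `median`, `iqr`, `relative_spread`, `narrow`).
#' @export
parameter_histograms <- function(elite, bins = 10, narrow_ratio = 0.25) {
  stopifnot(is.data.frame(elite))
  if (nrow(elite) == 0) stop("elite population is empty", call. = FALSE)
  logged <- c(paste0("k", 1:12), "D_Dl", "D_C", "D_DlC")
  hists <- list(); summ <- list()
  for (nm in dl_param_names()) {
    v <- elite[[nm]]
    if (is.null(v)) stop("elite table lacks parameter column ", nm,
                         call. = FALSE)
    log_scale <- nm %in% logged
    u <- if (log_scale) log10(v) else v
    rng <- range(u)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng), 1) * 1e-6
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    cnt <- graphics::hist(u, breaks = brk, plot = FALSE)$counts
    lo <- brk[-length(brk)]; hi <- brk[-1]
    if (log_scale) { lo <- 10^lo; hi <- 10^hi }
    hists[[nm]] <- tibble::tibble(parameter = nm, bin_lo = lo, bin_hi = hi,
                                  bin_mid = sqrt(lo * hi) * log_scale +
                                    (lo + hi) / 2 * (!log_scale),
                                  count = cnt, log_scale = log_scale)
    med <- stats::median(v)
    iqr <- stats::IQR(v)
    rel <- if (med != 0) iqr / abs(med) else Inf
    summ[[nm]] <- tibble::tibble(parameter = nm, median = med, iqr = iqr,
                                 relative_spread = rel,
                                 narrow = rel < narrow_ratio)
  }
  list(histograms = dplyr::bind_rows(hists),
       summary = dplyr::bind_rows(summ))
}

#' Read or write quantified gradient data
#'
#' Tabular layout of the embryo quantifications consumed by the
#' calibration: columns `position` (fraction of the ventral-to-dorsal
#' half axis), `nDl_mean` and optionally `nDl_sem`. CSV is canonical;
#' `.xlsx` files with the same sheet layout are read when the `readxl`
#' package is available.
#'
#' @param path File path.
#' @return `read_gradient_data()`: tibble with columns `position`,
#'   `nDl` and (if present) `sem`, sorted by position.
#' @export
read_gradient_data <- function(path) {
  stopifnot(file.exists(path))
  df <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package; use CSV instead",
           call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path)
  }
  if (!"position" %in% names(df)) {
    stop("data must have a 'position' column", call. = FALSE)
  }
  val_col <- intersect(c("nDl_mean", "nDl"), names(df))[1]
  if (is.na(val_col)) {
    stop("data must have an 'nDl_mean' (or 'nDl') column", call. = FALSE)
  }
  out <- tibble::tibble(position = df$position, nDl = df[[val_col]])
  sem_col <- intersect(c("nDl_sem", "sem"), names(df))[1]
  if (!is.na(sem_col)) out$sem <- df[[sem_col]]
  out[order(out$position), ]
}

#' @param profile Gradient tibble with columns `position`, `nDl` and
#'   optionally `sem`.
#' @rdname read_gradient_data
#' @export
write_gradient_data <- function(profile, path) {
  stopifnot(is.data.frame(profile),
            all(c("position", "nDl") %in% names(profile)))
  out <- data.frame(position = profile$position, nDl_mean = profile$nDl)
  if ("sem" %in% names(profile)) out$nDl_sem <- profile$sem
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
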