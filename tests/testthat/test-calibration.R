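test_that("quadratic loss sums squared deviations at data positions", {
  prof <- tibble::tibble(position = c(0.1, 0.5, 0.9), nDl = c(1, 0.5, 0.2))
  expect_equal(quadratic_loss(prof, prof), 0)

  shifted <- dplyr::mutate(prof, nDl = nDl + 0.1)
  expect_equal(quadratic_loss(shifted, prof), 0.03)

  # invariance under reordering of the experimental positions
  dense <- tibble::tibble(position = (1:50 - 0.5) / 50,
                          nDl = exp(-((1:50 - 0.5) / 50)^2))
  set.seed(3)
  shuffled <- dense[sample(nrow(dense)), ]
  expect_equal(quadratic_loss(prof, dense), quadratic_loss(prof, shuffled))

  expect_error(quadratic_loss(prof, prof[0, ]), "empty")
})

test_that("binary genomes decode affinely onto their bounds", {
  cfg <- ga_config(population_size = 4, generations = 1,
                   bits_per_parameter = 8)
  L <- cfg$genome_length
  lo <- decode_genome(rep(0L, L), cfg)
  hi <- decode_genome(rep(1L, L), cfg)
  expect_equal(unlist(lo[dl_param_names()]), setNames(cfg$bounds$lo,
                                                      dl_param_names()))
  expect_equal(unlist(hi[dl_param_names()]), setNames(cfg$bounds$hi,
                                                      dl_param_names()))

  # 8-bit slice holding 128 on linear bounds (0, 255 s) decodes to 128 s
  s <- 0.004
  bounds <- ga_bounds()
  bounds$lo <- rep(0, 18); bounds$hi <- rep(255 * s, 18)
  bounds$scale <- rep("linear", 18)
  cfg2 <- ga_config(population_size = 4, generations = 1,
                    bits_per_parameter = 8, bounds = bounds)
  genome <- rep(c(1L, rep(0L, 7)), 18)  # MSB set: integer value 128
  dec <- decode_genome(genome, cfg2)
  expect_equal(unname(unlist(dec[dl_param_names()])), rep(128 * s, 18))

  expect_error(decode_genome(rep(0L, L - 1), cfg), "length")
})

test_that("elite selection filters and sorts by cost", {
  pop <- tibble::tibble(cost = c(0.01, 0.07, 0.05))
  sel <- elite_selection(pop, 0.069)
  expect_equal(sel$cost, c(0.01, 0.05))
  expect_equal(nrow(elite_selection(pop, 0.001)), 0)
  expect_equal(elite_selection(pop, Inf)$cost, sort(pop$cost))
})

test_that("parameter histograms handle degenerate elites", {
  one <- tibble::as_tibble(as.list(unlist(dl_params()[dl_param_names()])))
  one$cost <- 0.01
  h <- parameter_histograms(one)
  expect_equal(sum(h$summary$iqr), 0)
  expect_true(all(h$summary$narrow))
  expect_equal(unique(as.vector(tapply(h$histograms$count,
                                       h$histograms$parameter, sum))), 1L)

  clones <- dplyr::bind_rows(one, one, one)
  h3 <- parameter_histograms(clones)
  expect_equal(max(h3$summary$iqr), 0)

  expect_error(parameter_histograms(one[0, ]), "empty")
})

test_that("a tiny calibration run is deterministic, monotone and
           recovers a forgiving synthetic target", {
  g <- dl_grid(10)
  dat <- simulate_gradient_data(truth = dl_params(), grid = g,
                                noise_sd = 0, seed = 1)
  cfg <- ga_config(population_size = 8, generations = 5, seed = 99,
                   epidemic_stagnation = 50)
  fit1 <- ga_evolve(dat, cfg, grid = g)
  fit2 <- ga_evolve(dat, cfg, grid = g)
  expect_identical(fit1$history, fit2$history)       # same seed, same run
  expect_true(all(diff(fit1$history$best_cost) <= 0)) # elitism
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_equal(nrow(tidy(fit1)), 18)
  expect_lt(glance(fit1)$best_cost, glance(fit1)$final_mean_cost + 1e-12)
})

test_that("with no variation operators a uniform population is invariant", {
  g <- dl_grid(5)
  dat <- simulate_phenom_gradient(10, noise_sd = 0)
  cfg <- ga_config(population_size = 6, generations = 3,
                   bits_per_parameter = 4, crossover_rate = 0,
                   mutation_rate = 0, seed = 5)
  genome <- rep(c(1L, 0L), length.out = cfg$genome_length)
  pop0 <- matrix(rep(genome, 6), nrow = 6, byrow = TRUE)
  fit <- ga_evolve(dat, cfg, grid = g, initial_population = pop0)
  expect_equal(fit$evaluations, 1L)  # one distinct genome ever evaluated
  expect_equal(length(unique(fit$history$best_cost)), 1L)
  expect_equal(unlist(fit$best$params[dl_param_names()]),
               unlist(decode_genome(genome, cfg)[dl_param_names()]))
})

test_that("failed simulations are penalized rather than fatal", {
  g <- dl_grid(5)
  dat <- simulate_phenom_gradient(10, noise_sd = 0)
  # an impossibly tight solver budget makes every simulation fail
  cfg <- ga_config(population_size = 4, generations = 2, seed = 2,
                   penalty_cost = 1e6,
                   solver = solver_config(steady_tol = 1e-16, t_max = 2,
                                          check_interval = 1))
  fit <- ga_evolve(dat, cfg, grid = g)
  expect_equal(fit$best$cost, 1e6)
})

test_that("gradient data files round-trip and tolerate layout variants", {
  prof <- simulate_phenom_gradient(12, noise_sd = 0.02, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_gradient_data(prof, f)
  back <- read_gradient_data(f)
  expect_equal(back$position, prof$position)
  expect_equal(back$nDl, prof$nDl)
  expect_equal(back$sem, prof$sem)

  # plain nDl column and unsorted rows are accepted and sorted
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(position = c(0.5, 0.1), nDl = c(2, 1)),
                   f2, row.names = FALSE)
  back2 <- read_gradient_data(f2)
  expect_equal(back2$position, c(0.1, 0.5))
  expect_false("sem" %in% names(back2))
})
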