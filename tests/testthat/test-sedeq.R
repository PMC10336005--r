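cond <- solution_conditions()

test_that("single ideal species matches the closed-form exponential", {
  m <- self_assoc_model(1L)
  run <- rotor_run(20000, n_points = 120)
  p <- simulate_profile(m, cond, run, 20e-6, unit_extinction = 30000)
  # closed form: c(r) = cref exp(sigma (r^2 - r0^2)/2) with cell-average
  # (exp(S)-1)/S pinned to the loading
  omega <- 20000 * 2 * pi / 60
  sigma <- 51800 * (1 - cond$vbar * cond$density) * omega^2 /
    (8.31446e7 * cond$temperature)
  S <- sigma * (run$base^2 - run$meniscus^2) / 2
  cref <- 20e-6 / (expm1(S) / S)
  expected <- 1.2 * 30000 * cref * exp(sigma * (run$radius^2 - run$meniscus^2) / 2)
  expect_equal(p$absorbance, expected, tolerance = 1e-10)
})

test_that("a near-massless species sediments into a flat profile", {
  m <- self_assoc_model(1L, unit_mass = 1e-6)
  p <- simulate_profile(m, cond, rotor_run(7000), 10e-6, unit_extinction = 30000)
  expect_equal(p$absorbance, rep(1.2 * 30000 * 10e-6, nrow(p)), tolerance = 1e-8)
})

test_that("mass conservation holds exactly and against numeric quadrature", {
  m <- self_assoc_model(c(1L, 2L, 4L), log10_kd = truth_log10_kd())
  for (speed in c(7000, 11000, 20000)) for (loading in c(12.6e-6, 55e-6)) {
    run <- rotor_run(speed, n_points = 2000)
    p <- simulate_profile(m, cond, run, loading, unit_extinction = 30000)
    # signal increases monotonically with radius (all sigma > 0)
    expect_true(all(diff(p$absorbance) > 0))
    # quadrature oracle: trapezoidal sector average of total concentration
    conc <- p$absorbance / (1.2 * 30000)   # tetramer-equivalent units
    r <- p$radius
    trap <- function(f) sum(diff(r) * (head(f, -1) + tail(f, -1)) / 2)
    avg <- trap(conc * r) / trap(r)
    expect_equal(avg, loading, tolerance = 1e-5)
  }
})

test_that("profiles at different speeds share the conservation integral", {
  m <- self_assoc_model(c(1L, 2L, 4L), log10_kd = truth_log10_kd())
  avgs <- sapply(c(3000, 7000, 11000, 20000), function(sp) {
    run <- rotor_run(sp, n_points = 3000)
    p <- simulate_profile(m, cond, run, 25e-6, unit_extinction = 30000)
    conc <- p$absorbance / (1.2 * 30000)
    r <- p$radius
    sum(diff(r) * (head(conc * r, -1) + tail(conc * r, -1)) / 2) /
      sum(diff(r) * (head(r, -1) + tail(r, -1)) / 2)
  })
  expect_equal(avgs, rep(25e-6, 4), tolerance = 1e-5)
})

test_that("noise-free global fit recovers the generating constants", {
  data <- gen_sedeq_dataset(paper_k(), noise_sd = 0, n_points = 40, seed = 1)
  fit <- global_fit(data, canonical_model())
  expect_true(fit$converged)
  expect_equal(unname(fit$log10_kd), truth_log10_kd(), tolerance = 1e-6)
  expect_equal(unname(fit$ratios["250"]), 0.45, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("per-cell baselines are recovered by the fit", {
  m <- self_assoc_model(c(1L, 2L, 4L), log10_kd = truth_log10_kd())
  profiles <- lapply(c(7000, 20000), function(sp) {
    simulate_profile(m, cond, rotor_run(sp, n_points = 50), 25e-6,
                     unit_extinction = 30000, baseline = 0.05)
  })
  fit <- global_fit(profiles, canonical_model())
  expect_equal(unname(fit$baselines), c(0.05, 0.05), tolerance = 1e-6)
})

test_that("F-stat interval matches the local quadratic of the RSS surface", {
  data <- gen_sedeq_dataset(paper_k(), noise_sd = 0.005, n_points = 40, seed = 5)
  m <- canonical_model()
  fit <- global_fit(data, m)
  ci <- fstat_confidence(data, m, cond, fit, param = 1)
  expect_false(ci$open_lower || ci$open_upper)
  # oracle: fit a parabola to the profiled RSS near the optimum and solve
  # for the crossing of the F threshold analytically
  pf <- pcmscaffold:::prepare_profiles(data, 280, 30000)
  prof_rss <- function(v) {
    obj <- function(sub) pcmscaffold:::sedeq_rss(c(v, sub), m, cond, pf)
    stats::nlminb(fit$log10_kd[2], obj)$objective
  }
  d <- (ci$upper - ci$lower) / 2
  v <- unname(fit$log10_kd[1]) + c(-d, 0, d)
  rss <- vapply(v, prof_rss, numeric(1))
  a <- (rss[1] + rss[3] - 2 * rss[2]) / (2 * d^2)  # curvature
  halfwidth <- sqrt((ci$rss_crit - fit$rss) / a)
  expect_equal(ci$upper - ci$lower, 2 * halfwidth, tolerance = 0.2)
})

test_that("shrinking the confidence level collapses the interval", {
  data <- gen_sedeq_dataset(paper_k(), noise_sd = 0.005, n_points = 30, seed = 6)
  m <- canonical_model()
  fit <- global_fit(data, m)
  wide <- fstat_confidence(data, m, cond, fit, 1, level = 0.68)
  tiny <- fstat_confidence(data, m, cond, fit, 1, level = 1e-6)
  expect_lt(tiny$upper - tiny$lower, (wide$upper - wide$lower) / 10)
  expect_equal((tiny$upper + tiny$lower) / 2, unname(fit$log10_kd[1]),
               tolerance = 0.01)
})

test_that("model comparison is deterministic and penalises the wrong ladder", {
  data <- gen_sedeq_dataset(paper_k(), noise_sd = 0.005, n_points = 40, seed = 9)
  # identical models give identical chi-squared
  cmp_same <- compare_models(data, list(canonical_model(), canonical_model()))
  expect_equal(cmp_same$ranking$reduced_chisq[1],
               cmp_same$ranking$reduced_chisq[2], tolerance = 1e-10)
  # a non-associating single-species model fits strongly associating data
  # at least 2x worse than the true ladder
  cmp <- compare_models(data, list(canonical_model(), self_assoc_model(1L)))
  expect_identical(cmp$ranking$model[1], "1-2-4")
  expect_gt(cmp$ranking$reduced_chisq[2] / cmp$ranking$reduced_chisq[1], 2)
})

test_that("pure tetramer data does not punish the non-associating model", {
  m1 <- self_assoc_model(1L)
  profiles <- lapply(c(7000, 11000, 20000), function(sp)
    simulate_profile(m1, cond, rotor_run(sp, n_points = 40), 10e-6,
                     unit_extinction = 30000))
  profiles <- withr::with_seed(4, lapply(profiles, function(p) {
    p$absorbance <- p$absorbance + stats::rnorm(nrow(p), 0, 0.005); p
  }))
  cmp <- compare_models(profiles, list(self_assoc_model(1L), canonical_model()))
  r <- cmp$ranking
  chi1 <- r$reduced_chisq[r$model == "1"]
  chibest <- min(r$reduced_chisq)
  expect_lt(chi1 / chibest, 1.05)
})

test_that("isodesmic alternative is rejected on cooperative data", {
  reject <- vapply(1:5, function(s) {
    data <- gen_sedeq_dataset(paper_k(), noise_sd = 0.005, n_points = 30,
                              seed = 100 + s)
    cmp <- compare_models(data, list(canonical_model(),
                                     self_assoc_model(isodesmic = TRUE)))
    r <- cmp$ranking
    r$reduced_chisq[grepl("isodesmic", r$model)] /
      r$reduced_chisq[r$model == "1-2-4"] > 1.5
  }, logical(1))
  expect_gte(mean(reject), 0.9)
})

test_that("profiles round-trip through the CSV schema", {
  data <- gen_sedeq_dataset(paper_k(), noise_sd = 0.002, n_points = 25, seed = 3,
                            wavelengths = 280)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(data, path)
  back <- read_profiles_csv(path)
  expect_length(back, length(data))
  expect_equal(back[[1]]$absorbance, data[[1]]$absorbance, tolerance = 1e-10)
  expect_equal(attr(back[[1]], "loading"), attr(data[[1]], "loading"))
  fit <- global_fit(back, canonical_model())
  expect_equal(unname(fit$log10_kd), truth_log10_kd(), tolerance = 0.05)
})
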