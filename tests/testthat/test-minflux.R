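test_that("trace length filter is inclusive at the cut", {
  tab <- make_traces(c(4, 5))
  out <- filter_traces(tab, 5)
  expect_identical(unique(out$trace_id), 2L)
  expect_identical(attr(out, "n_discarded_traces"), 1L)
  expect_identical(attr(out, "n_retained_traces"), 1L)

  # lengths 1..10: six traces of length >= 5 survive
  out10 <- filter_traces(make_traces(1:10), 5)
  expect_identical(attr(out10, "n_retained_traces"), 6L)

  # empty input passes through
  expect_identical(nrow(filter_traces(tab[0, ], 5)), 0L)

  # raising the cut never increases retained traces
  tab2 <- make_traces(c(2, 5, 7, 9, 12))
  kept <- vapply(1:12, function(m)
    attr(filter_traces(tab2, m), "n_retained_traces"), integer(1))
  expect_true(all(diff(kept) <= 0))

  expect_error(filter_traces(data.frame(x_nm = 1)), "trace_id")
})

test_that("photon-weighted collapse follows hand-computed weights", {
  # (0,0,0) w=100 and (10,0,0) w=300 -> (7.5, 0, 0)
  tab <- data.frame(trace_id = 1L, t_s = c(0, 1e-3),
                    x_nm = c(0, 10), y_nm = 0, z_nm = 0,
                    photons = c(100, 300))
  mol <- collapse_traces(tab)
  expect_equal(mol$x_nm, 7.5)
  expect_equal(mol$total_photons, 400)

  # equal photons reduce to the arithmetic mean
  tab2 <- make_traces(6); tab2$x_nm <- 1:6
  expect_equal(collapse_traces(tab2)$x_nm, mean(1:6))

  # all photons on one localization pin the position there
  tab3 <- data.frame(trace_id = 1L, t_s = c(0, 1e-3, 2e-3),
                     x_nm = c(5, 9, 1), y_nm = c(2, 4, 8), z_nm = 0,
                     photons = c(0, 1000, 0))
  mol3 <- collapse_traces(tab3)
  expect_equal(c(mol3$x_nm, mol3$y_nm), c(9, 4))

  # zero total photons: unweighted mean with a warning
  tab4 <- data.frame(trace_id = 1L, t_s = c(0, 1e-3), x_nm = c(0, 10),
                     y_nm = 0, z_nm = 0, photons = c(0, 0))
  expect_warning(mol4 <- collapse_traces(tab4), "zero total photons")
  expect_equal(mol4$x_nm, 5)
})

test_that("molecule positions stay inside the trace bounding box", {
  set.seed(14)
  recs <- gen_localization_traces(
    gen_cylinder_molecules(cylinder_truth(n_molecules = 40), seed = 2),
    imaging_model(n_background = 0), seed = 3)
  mol <- collapse_traces(recs)
  for (i in seq_len(nrow(mol))) {
    d <- recs[recs$trace_id == mol$trace_id[i], ]
    expect_gte(mol$x_nm[i], min(d$x_nm)); expect_lte(mol$x_nm[i], max(d$x_nm))
    expect_gte(mol$z_nm[i], min(d$z_nm)); expect_lte(mol$z_nm[i], max(d$z_nm))
  }
})

test_that("precision estimator recovers the injected scatter", {
  # identical localizations -> zero precision
  tab0 <- make_traces(c(5, 6))
  expect_equal(estimate_precision(tab0), 0)

  # two traces with known per-trace scalar s.d.: median of two = midpoint
  tr <- function(id, sds) data.frame(trace_id = id, t_s = 1:2 * 1e-3,
                                     x_nm = c(0, sds * sqrt(2)),
                                     y_nm = c(0, sds * sqrt(2)),
                                     z_nm = c(0, sds * sqrt(2)), photons = 10)
  tab2 <- rbind(tr(1, 5), tr(2, 9))
  expect_equal(estimate_precision(tab2), 7)

  # 500 traces of >= 20 localizations at sigma = 13 nm
  set.seed(5)
  tab <- make_traces(rep(25, 500), sd = 13)
  expect_equal(estimate_precision(tab), 13, tolerance = 1 / 13)

  # single-localization traces are excluded; all excluded is an error
  expect_error(estimate_precision(make_traces(c(1, 1))), "precision undefined")
})

test_that("circle fit is exact on noiseless circles and matches circumcircle", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  x <- 50 + 192 * cos(th); y <- -20 + 192 * sin(th)
  f <- fit_circle(x, y)
  expect_equal(f$center_x, 50, tolerance = 1e-9)
  expect_equal(f$center_y, -20, tolerance = 1e-9)
  expect_equal(f$radius, 192, tolerance = 1e-9)
  expect_lt(f$rms_residual, 1e-9)

  # three points: the circumcircle of the triangle
  set.seed(8)
  for (i in 1:20) {
    x3 <- stats::rnorm(3, 0, 50); y3 <- stats::rnorm(3, 0, 50)
    o <- oracle_circumcircle(x3, y3)
    f3 <- fit_circle(x3, y3)
    expect_equal(f3$center_x, o$center_x, tolerance = 1e-6)
    expect_equal(f3$center_y, o$center_y, tolerance = 1e-6)
    expect_equal(f3$radius, o$radius, tolerance = 1e-6)
  }

  expect_error(fit_circle(c(0, 1), c(0, 1)), "at least 3")
  expect_error(fit_circle(c(0, 1, 2), c(0, 1, 2)), "collinear")
})

test_that("circle fit tolerates localization noise", {
  set.seed(10)
  th <- stats::runif(500, 0, 2 * pi)
  f <- fit_circle(192 * cos(th) + stats::rnorm(500, 0, 13),
                  192 * sin(th) + stats::rnorm(500, 0, 13))
  expect_equal(f$radius, 192, tolerance = 3 / 192)
})

test_that("whisker bounds match hand-computed quartile arithmetic", {
  # radii 1..20 at angle 0, all z equal: Q1 = 5.75, Q3 = 15.25 (linear
  # interpolation), IQR = 9.5, whiskers [-8.5, 29.5]; p5/p95 = 1.95/19.05
  mol <- data.frame(x_nm = 1:20, y_nm = 0, z_nm = 0)
  fit <- structure(list(center_x = 0, center_y = 0, radius = 10,
                        rms_residual = 0), class = "circle_fit")
  st <- cylinder_stats(mol, fit)
  expect_equal(unname(st$whisker_radial_range), c(-8.5, 29.5))
  expect_equal(unname(st$radial_p5_p95), c(1.95, 19.05))
  expect_equal(st$radial_width, 17.1)
  expect_equal(st$outlier_fraction, 0)
  expect_equal(st$mean_radius, mean(1:20))

  # all molecules at one radius: degenerate shell of zero width
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- data.frame(x_nm = 100 * cos(th), y_nm = 100 * sin(th), z_nm = 0)
  st0 <- cylinder_stats(ring, fit)
  expect_equal(st0$radial_width, 0, tolerance = 1e-10)
  expect_equal(unname(diff(st0$whisker_radial_range)), 0, tolerance = 1e-10)
})

test_that("cylinder statistics recover a synthetic wild-type shell", {
  truth <- cylinder_truth(n_molecules = 500)
  mol <- gen_cylinder_molecules(truth, seed = 42)
  noisy <- mol
  set.seed(43)
  noisy$x_nm <- mol$x_nm + stats::rnorm(500, 0, 13)
  noisy$y_nm <- mol$y_nm + stats::rnorm(500, 0, 13)
  noisy$z_nm <- mol$z_nm + stats::rnorm(500, 0, 13)
  st <- cylinder_stats(noisy)
  expect_equal(st$mean_diameter, 384, tolerance = 0.06)
  expect_equal(st$radial_width, 109 * 0.9, tolerance = 0.15)
  expect_equal(st$height, 262 * 0.9, tolerance = 0.15)
  expect_lte(st$radial_width,
             st$whisker_radial_range[2] - st$whisker_radial_range[1])
})

test_that("shell concentration arithmetic uses Avogadro correctly", {
  expect_equal(concentration_in_shell(1, 1e9), 1.66054e-9, tolerance = 1e-4)
  expect_equal(concentration_in_shell(0, 1e9), 0)
  # the reported pericentriolar copy number in its shell volume is of
  # order 10 uM
  expect_equal(concentration_in_shell(270, 2.80e7) * 1e6, 16, tolerance = 0.05)
  expect_error(concentration_in_shell(5, 0), "positive")
})

test_that("density rendering preserves intensity and localises mass", {
  pt <- data.frame(x_nm = 1.2, y_nm = -3.4, z_nm = 0.7)
  v <- render_density(pt, voxel = 1, sigma = 2)
  expect_equal(sum(v$intensity), 1, tolerance = 1e-6)
  peak <- which(v$intensity == max(v$intensity), arr.ind = TRUE)[1, ]
  ctr <- v$origin + (peak - 1) * v$voxel
  expect_true(all(abs(ctr - c(1.2, -3.4, 0.7)) <= v$voxel))

  # linearity: two distant points give the sum of two single-point volumes
  pts <- data.frame(x_nm = c(0, 40), y_nm = 0, z_nm = 0)
  v2 <- render_density(pts, voxel = 1, sigma = 2)
  expect_equal(sum(v2$intensity), 2, tolerance = 1e-6)
  expect_equal(max(v2$intensity), max(v$intensity), tolerance = 1e-6)

  set.seed(3)
  many <- data.frame(x_nm = stats::rnorm(100, 0, 10),
                     y_nm = stats::rnorm(100, 0, 10),
                     z_nm = stats::rnorm(100, 0, 10))
  v3 <- render_density(many, voxel = 2, sigma = 4)
  expect_equal(sum(v3$intensity), 100, tolerance = 1e-6)

  expect_error(render_density(pt, voxel = 0), "positive")
})

test_that("labeling statistics reproduce the nuclear-pore control arithmetic", {
  ls <- labeling_statistics(81, 24, 16, 93)
  expect_equal(ls$label_fraction, 81 / 384)
  expect_equal(ls$single_trace_fraction, 1 - (81 / 384)^2)
  expect_identical(ls$expected_traces, 85)
  expect_equal(ls$overcount_fraction, (93 - 85) / 85)

  ls0 <- labeling_statistics(0, 24, 16, 0)
  expect_equal(ls0$label_fraction, 0)
  expect_equal(ls0$single_trace_fraction, 1)
  expect_identical(ls0$expected_traces, 0)

  full <- labeling_statistics(384, 24, 16, 800)
  expect_equal(full$single_trace_fraction, 0)

  expect_error(labeling_statistics(0, 24, 16, 5), "expected zero")
  expect_error(labeling_statistics(400, 24, 16, 5), "more clusters")
})

test_that("pipeline outputs are bit-identical for identical inputs", {
  mol <- gen_cylinder_molecules(cylinder_truth(n_molecules = 80), seed = 1)
  recs <- gen_localization_traces(mol, imaging_model(n_background = 10), seed = 2)
  a <- minflux_pipeline(recs)
  b <- minflux_pipeline(recs)
  expect_identical(a$molecules, b$molecules)
  expect_identical(a$stats, b$stats)
})
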