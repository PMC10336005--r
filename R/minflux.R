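#' Read and write MINFLUX localization tables
#'
#' Localization tables are flat CSV with columns `trace_id`, `t_s`, `x_nm`,
#' `y_nm`, `z_nm`, `photons`. A trace is the run of sequential localizations
#' of one fluorophore until it bleaches.
#'
#' @param path CSV file path.
#' @return `read_localizations` returns a data frame with the schema above.
#' @export
read_localizations <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("trace_id", "t_s", "x_nm", "y_nm", "z_nm", "photons")
  if (!all(need %in% names(tab)))
    stop("localization CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' @rdname read_localizations
#' @param records Localization data frame.
#' @export
write_localizations <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

check_localizations <- function(records) {
  if (!is.data.frame(records) || !"trace_id" %in% names(records))
    stop("localization table must be a data frame with a trace_id column",
         call. = FALSE)
  need <- c("x_nm", "y_nm", "z_nm", "photons")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Discard short localization traces
#'
#' Traces with fewer than `min_localizations` localizations arise mostly from
#' background and are discarded; 5 is the cut that best separates noise
#' traces from real fluorophores in the nuclear-pore control data. The
#' boundary is inclusive: a 5-localization trace is retained.
#'
#' @param records Localization data frame (see [read_localizations()]).
#' @param min_localizations Minimum trace length retained, default 5.
#' @return The filtered data frame, with attributes `n_discarded_traces` and
#'   `n_retained_traces`.
#' @export
filter_traces <- function(records, min_localizations = 5) {
  check_localizations(records)
  if (nrow(records) == 0) {
    attr(records, "n_discarded_traces") <- 0L
    attr(records, "n_retained_traces") <- 0L
    return(records)
  }
  len <- table(records$trace_id)
  keep_ids <- names(len)[len >= min_localizations]
  out <- records[as.character(records$trace_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded_traces") <- length(len) - length(keep_ids)
  attr(out, "n_retained_traces") <- length(keep_ids)
  out
}

#' Collapse traces to single-molecule positions
#'
#' Each retained trace is assumed to report one molecule (validated by the
#' nuclear-pore control, where multiple traces per molecule occur only ~9%
#' of the time). The molecule position is the photon-weighted mean of the
#' trace's localizations per axis, the weight of a localization being its
#' photon count divided by the trace's total photons. A trace with zero
#' total photons falls back to the unweighted mean, with a warning.
#'
#' @param records Filtered localization data frame.
#' @return Data frame of molecules: `trace_id`, `x_nm`, `y_nm`, `z_nm`,
#'   `n_localizations`, `total_photons`, and per-axis sample standard
#'   deviations `sd_x`, `sd_y`, `sd_z` (NA for single-localization traces).
#' @export
collapse_traces <- function(records) {
  check_localizations(records)
  if (nrow(records) == 0)
    return(data.frame(trace_id = integer(), x_nm = numeric(), y_nm = numeric(),
                      z_nm = numeric(), n_localizations = integer(),
                      total_photons = numeric(), sd_x = numeric(),
                      sd_y = numeric(), sd_z = numeric()))
  pieces <- split(records, records$trace_id)
  zero_photon <- FALSE
  rows <- lapply(pieces, function(d) {
    tot <- sum(d$photons)
    if (tot > 0) {
      w <- d$photons / tot
    } else {
      zero_photon <<- TRUE
      w <- rep(1 / nrow(d), nrow(d))
    }
    data.frame(trace_id = d$trace_id[1],
               x_nm = sum(w * d$x_nm), y_nm = sum(w * d$y_nm),
               z_nm = sum(w * d$z_nm),
               n_localizations = nrow(d), total_photons = tot,
               sd_x = stats::sd(d$x_nm), sd_y = stats::sd(d$y_nm),
               sd_z = stats::sd(d$z_nm))
  })
  if (zero_photon)
    warning("trace(s) with zero total photons: used unweighted mean",
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$trace_id), , drop = FALSE]
}

#' Localization precision from trace scatter
#'
#' Precision is defined as the median, over traces, of the per-trace
#' coordinate standard deviation; per-axis sample standard deviations are
#' averaged to one scalar per trace before the median is taken.
#' Single-localization traces (undefined s.d.) are excluded.
#'
#' @param records Filtered localization data frame.
#' @return Precision in nm (scalar).
#' @export
estimate_precision <- function(records) {
  mol <- collapse_traces(records)
  per_trace <- rowMeans(mol[, c("sd_x", "sd_y", "sd_z")])
  per_trace <- per_trace[!is.na(per_trace)]
  if (!length(per_trace))
    stop("no trace with >= 2 localizations: precision undefined", call. = FALSE)
  stats::median(per_trace)
}

#' Least-squares circle fit
#'
#' Fits a circle to x-y points: algebraic (Kasa) fit by linear least squares,
#' refined by geometric Gauss-Newton minimising the sum of squared radial
#' residuals. Used to locate the cylinder axis of the pericentriolar
#' distribution in the x-y plane.
#'
#' @param x,y Point coordinates (nm). `x` may also be a two-column matrix or
#'   a data frame with `x_nm`/`y_nm` columns.
#' @return A `circle_fit` object: `center_x`, `center_y`, `radius`,
#'   `rms_residual`.
#' @export
fit_circle <- function(x, y = NULL) {
  if (is.null(y)) {
    if (is.data.frame(x) && all(c("x_nm", "y_nm") %in% names(x))) {
      y <- x$y_nm; x <- x$x_nm
    } else if (is.matrix(x) && ncol(x) == 2) {
      y <- x[, 2]; x <- x[, 1]
    } else stop("supply x and y, a 2-column matrix, or x_nm/y_nm columns",
                call. = FALSE)
  }
  if (length(x) < 3) stop("circle fit needs at least 3 points", call. = FALSE)
  # Kasa: x^2 + y^2 = 2 a x + 2 b y + c, linear in (a, b, c)
  A <- cbind(2 * x, 2 * y, 1)
  if (qr(A)$rank < 3) stop("degenerate (collinear) points: no unique circle",
                           call. = FALSE)
  sol <- qr.solve(A, x^2 + y^2)
  a <- sol[1]; b <- sol[2]
  r <- sqrt(sol[3] + a^2 + b^2)
  # geometric refinement: minimise sum (dist_i - r)^2 over (a, b, r)
  for (iter in 1:50) {
    d <- sqrt((x - a)^2 + (y - b)^2)
    if (any(d == 0)) break
    res <- d - r
    J <- cbind(-(x - a) / d, -(y - b) / d, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < 1e-12 * max(1, r)) break
  }
  d <- sqrt((x - a)^2 + (y - b)^2)
  structure(list(center_x = unname(a), center_y = unname(b), radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2))),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.2f, %.2f) nm, radius %.2f nm, rms %.2f nm\n",
              x$center_x, x$center_y, x$radius, x$rms_residual))
  invisible(x)
}

tukey_whiskers <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
}

#' Cylindrical shell statistics of molecule positions
#'
#' Computes the geometry of a cylindrical molecule distribution about the
#' z-axis through a fitted circle center. Radial distances to that axis and
#' z positions get Tukey box-plot whiskers (quartiles +/- 1.5 x IQR, linear
#' interpolation quantiles); molecules outside the whisker range in radius
#' or height are flagged outliers and excluded once, and all summary
#' statistics are computed from the retained molecules. The reported radial
#' width and height use the 5th-95th percentiles of the retained
#' distributions; the shell volume is pi (R_out^2 - R_in^2) x height for
#' the percentile shell, and the in-shell count and molar concentration
#' refer to molecules inside that shell. Heights are measured relative to
#' the median z of retained molecules.
#'
#' @param molecules Data frame of molecule positions (`x_nm`, `y_nm`, `z_nm`).
#' @param fit A [fit_circle()] result locating the cylinder axis; fitted from
#'   `molecules` when omitted.
#' @return A `cylinder_stats` object: mean radius and diameter, whisker
#'   ranges, p5-p95 radial width and height, outlier fraction, in-shell
#'   molecule count, shell volume (nm^3), concentration (M), and a
#'   `low_confidence` flag for < 10 molecules.
#' @export
cylinder_stats <- function(molecules, fit = NULL) {
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(molecules)))
  n <- nrow(molecules)
  if (n < 3) stop("need at least 3 molecules", call. = FALSE)
  if (is.null(fit)) fit <- fit_circle(molecules)
  r <- sqrt((molecules$x_nm - fit$center_x)^2 + (molecules$y_nm - fit$center_y)^2)
  z <- molecules$z_nm
  wr <- tukey_whiskers(r)
  wz <- tukey_whiskers(z)
  outlier <- r < wr[1] | r > wr[2] | z < wz[1] | z > wz[2]
  rk <- r[!outlier]
  zk <- z[!outlier] - stats::median(z[!outlier])
  p_r <- stats::quantile(rk, c(0.05, 0.95), type = 7, names = FALSE)
  p_z <- stats::quantile(zk, c(0.05, 0.95), type = 7, names = FALSE)
  width_p <- p_r[2] - p_r[1]
  height_p <- p_z[2] - p_z[1]
  vol <- pi * (p_r[2]^2 - p_r[1]^2) * height_p
  in_shell <- sum(rk >= p_r[1] & rk <= p_r[2] & zk >= p_z[1] & zk <= p_z[2])
  structure(list(
    center = c(x = fit$center_x, y = fit$center_y),
    fit_radius = fit$radius,
    mean_radius = mean(rk), mean_diameter = 2 * mean(rk),
    whisker_radial_range = wr, whisker_radial_width = wr[2] - max(wr[1], 0),
    whisker_height_range = wz, whisker_height = wz[2] - wz[1],
    radial_p5_p95 = p_r, radial_width = width_p,
    height = height_p,
    n_molecules = n, n_retained = sum(!outlier),
    outlier_fraction = mean(outlier),
    in_shell_count = in_shell,
    shell_volume_nm3 = vol,
    concentration_M = if (vol > 0) concentration_in_shell(in_shell, vol)
                      else NA_real_,
    low_confidence = n < 10), class = "cylinder_stats")
}

#' @export
print.cylinder_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Cylinder statistics (%d molecules, %.1f%% outliers excluded)%s\n",
    "  mean diameter  %.1f nm\n",
    "  radial width   %.1f nm (p5-p95)\n",
    "  height         %.1f nm (p5-p95)\n",
    "  shell volume   %.3g nm^3; %d molecules in shell -> %.3g M\n"),
    x$n_molecules, 100 * x$outlier_fraction,
    if (x$low_confidence) "  [low confidence: < 10 molecules]" else "",
    x$mean_diameter, x$radial_width, x$height,
    x$shell_volume_nm3, x$in_shell_count, x$concentration_M))
  invisible(x)
}

#' Molar concentration of molecules in a shell volume
#'
#' @param count Number of molecules.
#' @param volume Volume in nm^3 (1 nm^3 = 1e-24 L), or a
#'   [cylinder_stats()] object whose shell volume is used.
#' @return Concentration in molar.
#' @examples
#' concentration_in_shell(1, 1e9)  # 1 molecule per um^3 ~ 1.66 nM
#' @export
concentration_in_shell <- function(count, volume) {
  if (inherits(volume, "cylinder_stats")) volume <- volume$shell_volume_nm3
  if (!is.finite(volume) || volume <= 0)
    stop("shell volume must be positive", call. = FALSE)
  if (count < 0) stop("count must be non-negative", call. = FALSE)
  count / (6.02214076e23 * volume * 1e-24)
}

gaussian_kernel_1d <- function(sigma, voxel) {
  h <- max(1L, ceiling(3 * sigma / voxel))
  k <- exp(-((-h:h) * voxel)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 1D convolution of a 3D array along one axis (zero padding).
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- d[axis]
  h <- (length(kernel) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    src <- seq_len(n) - (j - h - 1L)
    ok <- which(src >= 1L & src <= n)
    if (!length(ok)) next
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Render a localization density volume
#'
#' Bins positions into cubic voxels and convolves with an isotropic 3D
#' Gaussian kernel (separable, normalised to unit sum), the rendering used
#' for pseudo-image display of MINFLUX data. The volume extent is padded by
#' the kernel half-width so the smoothed intensity sum equals the number of
#' binned points.
#'
#' @param points Data frame with `x_nm`, `y_nm`, `z_nm` (molecules or raw
#'   localizations).
#' @param voxel Voxel edge length, nm (default 0.5).
#' @param sigma Gaussian kernel standard deviation, nm (default 4).
#' @return A `density_volume`: 3D `intensity` array, `origin` (nm, center of
#'   the first voxel) and `voxel` size.
#' @export
render_density <- function(points, voxel = 0.5, sigma = 4) {
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(points)))
  if (nrow(points) == 0) stop("no points to render", call. = FALSE)
  if (voxel <= 0 || sigma <= 0) stop("voxel and sigma must be positive",
                                     call. = FALSE)
  kern <- gaussian_kernel_1d(sigma, voxel)
  pad <- (length(kern) - 1L) / 2L
  xyz <- as.matrix(points[, c("x_nm", "y_nm", "z_nm")])
  lo <- apply(xyz, 2, min) - (pad + 0.5) * voxel
  ijk <- floor(sweep(xyz, 2, lo) / voxel) + 1L
  dims <- apply(ijk, 2, max) + pad
  arr <- array(0, dims)
  for (row in seq_len(nrow(ijk))) {
    i <- ijk[row, 1]; j <- ijk[row, 2]; k <- ijk[row, 3]
    arr[i, j, k] <- arr[i, j, k] + 1
  }
  for (ax in 1:3) arr <- convolve_axis(arr, kern, ax)
  structure(list(intensity = arr, origin = lo + voxel / 2, voxel = voxel),
            class = "density_volume")
}

#' Labeling-efficiency and overcounting statistics (nuclear-pore control)
#'
#' Calibration arithmetic for the Nup96-style control: `n_pores` pores each
#' carry `dimers_per_pore` dimers; `n_clusters` labelled spots were seen, so
#' the label fraction is p = clusters / (pores x dimers). Under independent
#' labeling a cluster has a single trace with probability 1 - p^2 (only one
#' of the two dimer copies labelled) and two traces with probability p^2,
#' so the expected trace count is clusters x (1 + p^2); the excess of the
#' observed count over this expectation is the per-molecule overcount
#' (blinking into extra traces).
#'
#' @param n_clusters Labelled clusters counted in the rendered image.
#' @param n_pores Pores observed.
#' @param dimers_per_pore Dimers per pore (16 for Nup96: two rings of 8).
#' @param observed_traces Traces retained after filtering.
#' @return A `labeling_stats` object: `label_fraction`,
#'   `single_trace_fraction`, `expected_traces` (rounded), and
#'   `overcount_fraction`.
#' @examples
#' labeling_statistics(81, 24, 16, 93)
#' @export
labeling_statistics <- function(n_clusters, n_pores, dimers_per_pore,
                                observed_traces) {
  if (any(c(n_clusters, n_pores, dimers_per_pore, observed_traces) < 0))
    stop("all counts must be non-negative", call. = FALSE)
  if (n_pores * dimers_per_pore == 0)
    stop("n_pores * dimers_per_pore must be positive", call. = FALSE)
  p <- n_clusters / (n_pores * dimers_per_pore)
  if (p > 1) stop("more clusters than labelable sites", call. = FALSE)
  expected <- round(n_clusters * (1 + p^2))
  if (expected == 0 && observed_traces > 0)
    stop("expected zero traces but some were observed", call. = FALSE)
  over <- if (expected > 0) (observed_traces - expected) / expected else 0
  structure(list(label_fraction = p,
                 single_trace_fraction = 1 - p^2,
                 expected_traces = expected,
                 overcount_fraction = over),
            class = "labeling_stats")
}

#' @export
print.labeling_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Labeling statistics:\n  label fraction        %.1f%%\n",
    "  single-trace fraction %.1f%%\n  expected traces       %d\n",
    "  overcount             %.1f%%\n"),
    100 * x$label_fraction, 100 * x$single_trace_fraction,
    x$expected_traces, 100 * x$overcount_fraction))
  invisible(x)
}

#' Run the full MINFLUX processing pipeline
#'
#' Filter short traces, collapse to photon-weighted molecule positions,
#' estimate localization precision, fit the cylinder axis circle in x-y and
#' compute cylindrical shell statistics.
#'
#' @param records Raw localization data frame.
#' @param min_localizations Trace-length filter cut, default 5.
#' @return List with `molecules`, `precision_nm`, `circle`, `stats`, and
#'   filtering counts.
#' @export
minflux_pipeline <- function(records, min_localizations = 5) {
  filtered <- filter_traces(records, min_localizations)
  if (nrow(filtered) == 0) stop("no traces survive the length filter", call. = FALSE)
  molecules <- collapse_traces(filtered)
  precision <- estimate_precision(filtered)
  circle <- fit_circle(molecules)
  stats <- cylinder_stats(molecules, circle)
  list(molecules = molecules, precision_nm = precision, circle = circle,
       stats = stats,
       n_discarded_traces = attr(filtered, "n_discarded_traces"),
       n_retained_traces = attr(filtered, "n_retained_traces"))
}
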