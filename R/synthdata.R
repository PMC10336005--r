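#' Ground-truth cylinder geometry for synthetic molecule placement
#'
#' Defaults describe the wild-type pericentriolar distribution: a hollow
#' cylinder of mid radius 192 nm (384 nm diameter), 109 nm radial wall and
#' 262 nm height. `mode = "clumped"` emulates the assembly-defective
#' phenotype: molecules concentrate in 1-2 angular lobes and overall density
#' is reduced by `density_scale`.
#'
#' @param mid_radius Mid-wall radius, nm.
#' @param wall Radial wall thickness, nm.
#' @param height Cylinder height, nm.
#' @param n_molecules Number of molecules placed (scaled by `density_scale`
#'   in clumped mode).
#' @param mode `"WT"` or `"clumped"`.
#' @param n_lobes Number of angular lobes in clumped mode (1 or 2).
#' @param lobe_sd Angular spread of each lobe, radians.
#' @param density_scale Density factor applied in clumped mode.
#' @return A `cylinder_truth` object.
#' @export
cylinder_truth <- function(mid_radius = 192, wall = 109, height = 262,
                           n_molecules = 400, mode = c("WT", "clumped"),
                           n_lobes = 2, lobe_sd = 0.5, density_scale = 0.5) {
  mode <- match.arg(mode)
  if (wall >= 2 * mid_radius) stop("wall must be < 2 x mid radius", call. = FALSE)
  if (n_molecules < 0) stop("n_molecules must be >= 0", call. = FALSE)
  structure(list(mid_radius = mid_radius, wall = wall, height = height,
                 n_molecules = as.integer(n_molecules), mode = mode,
                 n_lobes = n_lobes, lobe_sd = lobe_sd,
                 density_scale = density_scale),
            class = "cylinder_truth")
}

#' Generate ground-truth molecules on a hollow cylinder
#'
#' Molecules are placed uniformly in the annular shell: radius uniform in
#' r^2 between the inner and outer wall (uniform areal density), z uniform
#' over the height, angle uniform for WT or drawn from 1-2 wrapped-Gaussian
#' lobes for the clumped mode. Seed-deterministic; the truth object is
#' attached to the output.
#'
#' @param truth A [cylinder_truth()] object.
#' @param seed Integer seed.
#' @return Data frame `molecule_id`, `x_nm`, `y_nm`, `z_nm`, `r_nm`,
#'   `theta`, with attribute `truth`.
#' @export
gen_cylinder_molecules <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "cylinder_truth"))
  n <- truth$n_molecules
  if (truth$mode == "clumped") n <- as.integer(round(n * truth$density_scale))
  out <- withr::with_seed(seed, {
    if (n == 0) {
      data.frame(molecule_id = integer(), x_nm = numeric(), y_nm = numeric(),
                 z_nm = numeric(), r_nm = numeric(), theta = numeric())
    } else {
      r_in <- truth$mid_radius - truth$wall / 2
      r_out <- truth$mid_radius + truth$wall / 2
      r <- sqrt(stats::runif(n, r_in^2, r_out^2))
      theta <- if (truth$mode == "WT") {
        stats::runif(n, 0, 2 * pi)
      } else {
        centers <- stats::runif(truth$n_lobes, 0, 2 * pi)
        (sample(centers, n, replace = TRUE) +
           stats::rnorm(n, 0, truth$lobe_sd)) %% (2 * pi)
      }
      z <- stats::runif(n, -truth$height / 2, truth$height / 2)
      data.frame(molecule_id = seq_len(n), x_nm = r * cos(theta),
                 y_nm = r * sin(theta), z_nm = z, r_nm = r, theta = theta)
    }
  })
  attr(out, "truth") <- truth
  out
}

#' Imaging model for synthetic MINFLUX acquisition
#'
#' Statistical model of the acquisition process: each molecule is labelled
#' with probability `labeling_efficiency`; a labelled molecule produces one
#' trace, plus a second with probability `extra_trace_prob` (the ~9%
#' blinking overcount measured in the nuclear-pore control); localizations
#' per trace follow a shifted Poisson `1 + Poisson(mean - 1)`; photon counts
#' are log-normal; localization scatter is isotropic Gaussian with
#' `noise_sd` (the ~13 nm precision); background traces are short by
#' construction so the length-5 filter discriminates them.
#'
#' @param labeling_efficiency Probability a molecule carries a label.
#' @param extra_trace_prob Probability a labelled molecule yields a second
#'   trace.
#' @param mean_localizations Mean localizations per signal trace.
#' @param photon_meanlog,photon_sdlog Log-normal photon-count parameters.
#' @param noise_sd Per-axis localization noise, nm.
#' @param n_background Number of background noise traces.
#' @param background_mean_localizations Mean localizations per background
#'   trace (short, mostly below the filter cut).
#' @return An `imaging_model` object.
#' @export
imaging_model <- function(labeling_efficiency = 1, extra_trace_prob = 0.09,
                          mean_localizations = 20, photon_meanlog = log(2000),
                          photon_sdlog = 0.5, noise_sd = 13,
                          n_background = 50,
                          background_mean_localizations = 2) {
  stopifnot(labeling_efficiency >= 0, labeling_efficiency <= 1,
            extra_trace_prob >= 0, extra_trace_prob <= 1,
            mean_localizations >= 1, noise_sd >= 0, n_background >= 0)
  structure(list(labeling_efficiency = labeling_efficiency,
                 extra_trace_prob = extra_trace_prob,
                 mean_localizations = mean_localizations,
                 photon_meanlog = photon_meanlog, photon_sdlog = photon_sdlog,
                 noise_sd = noise_sd, n_background = as.integer(n_background),
                 background_mean_localizations = background_mean_localizations),
            class = "imaging_model")
}

#' Generate synthetic MINFLUX localization traces
#'
#' Applies an [imaging_model()] to ground-truth molecules: Bernoulli
#' labeling, blinking into 1-2 traces, shifted-Poisson localization counts,
#' log-normal photons and isotropic Gaussian position noise, plus short
#' background traces scattered over the bounding volume. Ground-truth
#' provenance (`molecule_id`, `is_background`) is retained per localization.
#'
#' @param molecules Molecule table from [gen_cylinder_molecules()] (any data
#'   frame with `molecule_id`, `x_nm`, `y_nm`, `z_nm`).
#' @param imaging An [imaging_model()].
#' @param seed Integer seed.
#' @return Localization data frame: `trace_id`, `t_s`, `x_nm`, `y_nm`,
#'   `z_nm`, `photons`, `molecule_id`, `is_background`.
#' @export
gen_localization_traces <- function(molecules, imaging = imaging_model(),
                                    seed = 1) {
  stopifnot(inherits(imaging, "imaging_model"))
  withr::with_seed(seed, {
    rows <- list()
    trace_id <- 0L
    t0 <- 0
    n_mol <- nrow(molecules)
    labeled <- if (n_mol) stats::runif(n_mol) < imaging$labeling_efficiency else logical(0)
    for (i in seq_len(n_mol)) {
      if (!labeled[i]) next
      n_traces <- 1L + stats::rbinom(1, 1, imaging$extra_trace_prob)
      for (tr in seq_len(n_traces)) {
        trace_id <- trace_id + 1L
        n_loc <- 1L + stats::rpois(1, imaging$mean_localizations - 1)
        ph <- round(stats::rlnorm(n_loc, imaging$photon_meanlog,
                                  imaging$photon_sdlog))
        rows[[length(rows) + 1L]] <- data.frame(
          trace_id = trace_id,
          t_s = t0 + seq_len(n_loc) * 1e-3,
          x_nm = molecules$x_nm[i] + stats::rnorm(n_loc, 0, imaging$noise_sd),
          y_nm = molecules$y_nm[i] + stats::rnorm(n_loc, 0, imaging$noise_sd),
          z_nm = molecules$z_nm[i] + stats::rnorm(n_loc, 0, imaging$noise_sd),
          photons = ph, molecule_id = molecules$molecule_id[i],
          is_background = FALSE)
        t0 <- t0 + n_loc * 1e-3 + 0.01
      }
    }
    if (imaging$n_background > 0) {
      if (n_mol) {
        lo <- c(min(molecules$x_nm), min(molecules$y_nm), min(molecules$z_nm)) - 50
        hi <- c(max(molecules$x_nm), max(molecules$y_nm), max(molecules$z_nm)) + 50
      } else {
        lo <- c(-250, -250, -150); hi <- c(250, 250, 150)
      }
      for (b in seq_len(imaging$n_background)) {
        trace_id <- trace_id + 1L
        n_loc <- 1L + stats::rpois(1, imaging$background_mean_localizations - 1)
        pos <- stats::runif(3, lo, hi)
        ph <- round(stats::rlnorm(n_loc, imaging$photon_meanlog - 1,
                                  imaging$photon_sdlog))
        rows[[length(rows) + 1L]] <- data.frame(
          trace_id = trace_id,
          t_s = t0 + seq_len(n_loc) * 1e-3,
          x_nm = pos[1] + stats::rnorm(n_loc, 0, imaging$noise_sd),
          y_nm = pos[2] + stats::rnorm(n_loc, 0, imaging$noise_sd),
          z_nm = pos[3] + stats::rnorm(n_loc, 0, imaging$noise_sd),
          photons = ph, molecule_id = NA_integer_, is_background = TRUE)
        t0 <- t0 + n_loc * 1e-3 + 0.01
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(trace_id = integer(), t_s = numeric(), x_nm = numeric(),
                 y_nm = numeric(), z_nm = numeric(), photons = numeric(),
                 molecule_id = integer(), is_background = logical())
    rownames(out) <- NULL
    attr(out, "imaging") <- imaging
    attr(out, "seed") <- seed
    out
  })
}

#' Generate a synthetic sedimentation-equilibrium dataset
#'
#' Simulates noise-free equilibrium profiles for every combination of rotor
#' speed, loading concentration and wavelength in the design, then adds
#' i.i.d. Gaussian absorbance noise. The default design mirrors the
#' well-behaved experimental cells: loadings 12.6, 25 and 55 uM at 7,000,
#' 11,000 and 20,000 rpm, detected at 280 and 250 nm.
#'
#' @param k A [dissociation_constants()] object (tetramer-octamer-hexadecamer
#'   ladder) or a [self_assoc_model()] with constants set.
#' @param speeds Rotor speeds, rpm.
#' @param loadings Loading concentrations, M (free-unit units).
#' @param wavelengths Detection wavelengths, nm.
#' @param noise_sd Gaussian absorbance noise, AU.
#' @param cond A [solution_conditions()].
#' @param unit_extinction Free-unit extinction at the reference wavelength
#'   (280 nm), M^-1 cm^-1.
#' @param extinction_ratio True 250/280 extinction ratio.
#' @param pathlength Optical pathlength, cm.
#' @param n_points Radial grid points per profile.
#' @param seed Integer seed.
#' @return List of `equilibrium_profile` objects with attribute `truth`
#'   (model, ratio, noise, seed).
#' @export
gen_sedeq_dataset <- function(k, speeds = c(7000, 11000, 20000),
                              loadings = c(12.6e-6, 25e-6, 55e-6),
                              wavelengths = c(280, 250), noise_sd = 0.005,
                              cond = solution_conditions(),
                              unit_extinction = 30000, extinction_ratio = 0.45,
                              pathlength = 1.2, n_points = 100L, seed = 1) {
  model <- if (inherits(k, "dissociation_constants"))
    self_assoc_model(c(1L, 2L, 4L), log10_kd = log10(c(k$k8, k$k16)))
  else k
  stopifnot(inherits(model, "self_assoc_model"), !anyNA(model$log10_kd))
  withr::with_seed(seed, {
    profiles <- list()
    for (sp in speeds) for (ld in loadings) for (wl in wavelengths) {
      run <- rotor_run(sp, pathlength = pathlength, wavelength = wl,
                       n_points = n_points)
      ext <- unit_extinction * if (wl == 280) 1 else extinction_ratio
      p <- simulate_profile(model, cond, run, ld, unit_extinction = ext)
      if (noise_sd > 0)
        p$absorbance <- p$absorbance + stats::rnorm(nrow(p), 0, noise_sd)
      profiles[[length(profiles) + 1L]] <- p
    }
    attr(profiles, "truth") <- list(model = model,
                                    extinction_ratio = extinction_ratio,
                                    unit_extinction = unit_extinction,
                                    noise_sd = noise_sd, seed = seed)
    profiles
  })
}

#' Generate a mass-photometry-style particle mass sample
#'
#' Draws single particles from the equilibrium species distribution at the
#' given loading (probabilities proportional to the species number
#' concentrations) and reports masses `stoichiometry x unit_mass` blurred by
#' Gaussian measurement error. Under the cooperative
#' tetramer-octamer-hexadecamer ladder the sample is trimodal at 1x, 2x and
#' 4x the unit mass, with no 3x mode.
#'
#' @param k A [dissociation_constants()] object.
#' @param total Total loading, M (tetramer units).
#' @param unit_mass Building-block mass, Da.
#' @param mass_sd Gaussian mass error, Da.
#' @param n_particles Number of particles drawn.
#' @param seed Integer seed.
#' @return Data frame `stoichiometry`, `mass_da`, with attribute `truth`
#'   (the underlying species state).
#' @export
gen_mass_histogram <- function(k, total, unit_mass = 51800, mass_sd = 25000,
                               n_particles = 5000, seed = 1) {
  stopifnot(inherits(k, "dissociation_constants"), total > 0, n_particles >= 0)
  st <- species_distribution(total, k)
  probs <- c(st$c4, st$c8, st$c16)
  probs <- probs / sum(probs)
  out <- withr::with_seed(seed, {
    n <- sample(c(1L, 2L, 4L), n_particles, replace = TRUE, prob = probs)
    data.frame(stoichiometry = n,
               mass_da = n * unit_mass + stats::rnorm(n_particles, 0, mass_sd))
  })
  attr(out, "truth") <- st
  out
}
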