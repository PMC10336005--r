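#' Solution conditions for sedimentation equilibrium
#'
#' @param vbar Partial specific volume of the protein, mL/g.
#' @param density Solvent density, g/mL.
#' @param temperature Absolute temperature, K.
#' @return A `solution_conditions` object.
#' @export
solution_conditions <- function(vbar = 0.73, density = 1.015,
                                temperature = 277.15) {
  if (vbar * density <= 0 || vbar * density >= 1)
    stop("buoyancy term 1 - vbar*density must lie in (0, 1)", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive (K)", call. = FALSE)
  structure(list(vbar = vbar, density = density, temperature = temperature),
            class = "solution_conditions")
}

#' Rotor run geometry and optics
#'
#' Describes one equilibrium scan: rotor speed, solution column limits,
#' optical pathlength, detection wavelength and the radial grid.
#'
#' @param speed_rpm Rotor speed, revolutions per minute.
#' @param meniscus,base Radial positions of meniscus and cell base, cm.
#' @param pathlength Optical pathlength, cm.
#' @param wavelength Detection wavelength, nm.
#' @param n_points Number of radial grid points.
#' @return A `rotor_run` object carrying the radial grid in `radius`.
#' @export
rotor_run <- function(speed_rpm, meniscus = 6.9, base = 7.15,
                      pathlength = 1.2, wavelength = 280, n_points = 200L) {
  if (speed_rpm <= 0) stop("speed must be positive", call. = FALSE)
  if (meniscus >= base) stop("meniscus radius must be below base radius", call. = FALSE)
  structure(list(speed_rpm = speed_rpm, meniscus = meniscus, base = base,
                 pathlength = pathlength, wavelength = wavelength,
                 radius = seq(meniscus, base, length.out = as.integer(n_points))),
            class = "rotor_run")
}

#' Reversible self-association model
#'
#' Defines the species ladder of a reversible self-association in units of
#' the free building block (stoichiometry 1). Each higher species n obeys
#' mass action \eqn{K_n = c_1^n / c_n} with `K_n` in M^(n-1); for the
#' canonical tetramer--octamer--hexadecamer ladder (`stoich = c(1, 2, 4)`)
#' these are exactly the constants `k8` (M) and `k16` (M^3) of the lattice
#' model. An isodesmic model instead uses one stepwise constant K for every
#' addition: \eqn{c_n = c_1 (c_1/K)^{n-1}} for n = 1..`nmax`.
#'
#' @param stoich Integer stoichiometries, must start with 1 (the free unit).
#' @param log10_kd Numeric, `length(stoich) - 1` log10 dissociation constants
#'   (M^(n-1)) for the species beyond the free unit; or a single value when
#'   `isodesmic = TRUE`. May be `NA` for a model to be fitted.
#' @param isodesmic If `TRUE`, a single-K isodesmic ladder up to `nmax`.
#' @param nmax Largest oligomer of the isodesmic ladder.
#' @param unit_mass Molar mass of the free unit, Da (default 51,800, the
#'   calculated mass of the 2:2 heterotetramer).
#' @param name Optional display name.
#' @return A `self_assoc_model` object.
#' @examples
#' m <- self_assoc_model(c(1, 2, 4), log10_kd = log10(c(370e-6, 3.0e-13)))
#' @export
self_assoc_model <- function(stoich = c(1L, 2L, 4L), log10_kd = NULL,
                             isodesmic = FALSE, nmax = 8L,
                             unit_mass = 51800, name = NULL) {
  if (isodesmic) {
    stoich <- seq_len(as.integer(nmax))
    npar <- 1L
    if (is.null(name)) name <- sprintf("isodesmic (n <= %d)", nmax)
  } else {
    stoich <- as.integer(sort(unique(stoich)))
    if (stoich[1] != 1L) stop("model must contain the free unit (stoichiometry 1)",
                              call. = FALSE)
    npar <- length(stoich) - 1L
    if (is.null(name)) name <- paste(stoich, collapse = "-")
  }
  if (is.null(log10_kd)) log10_kd <- rep(NA_real_, npar)
  if (length(log10_kd) != npar)
    stop(sprintf("expected %d log10 Kd value(s), got %d", npar, length(log10_kd)),
         call. = FALSE)
  structure(list(stoich = stoich, log10_kd = log10_kd, isodesmic = isodesmic,
                 unit_mass = unit_mass, name = name),
            class = "self_assoc_model")
}

#' @export
print.self_assoc_model <- function(x, ...) {
  cat(sprintf("Self-association model %s (unit mass %.0f Da)\n", x$name, x$unit_mass))
  if (x$isodesmic) {
    cat(sprintf("  stepwise log10 Kd = %s\n", format(x$log10_kd)))
  } else if (length(x$log10_kd)) {
    cat(sprintf("  species n = %d: log10 Kd = %s (M^%d)\n",
                x$stoich[-1], format(x$log10_kd), x$stoich[-1] - 1L))
  }
  invisible(x)
}

# Species concentrations from the free-unit concentration under mass action.
species_conc <- function(model, c1) {
  n <- model$stoich
  if (model$isodesmic) {
    K <- 10^model$log10_kd
    c1 * (c1 / K)^(n - 1)
  } else {
    K <- c(1, 10^model$log10_kd)  # K_1 = 1 by convention
    c1^n / K
  }
}

# Reduced buoyant coefficient sigma_n = n M (1 - vbar rho) omega^2 / (R T),
# cm^-2, for concentration profiles c_n(r) = c_n(r0) exp(sigma_n (r^2-r0^2)/2).
reduced_sigma <- function(model, cond, speed_rpm) {
  R_gas <- 8.31446e7  # erg / (mol K)
  omega <- speed_rpm * 2 * pi / 60
  model$stoich * model$unit_mass * (1 - cond$vbar * cond$density) * omega^2 /
    (R_gas * cond$temperature)
}

# Sector-shaped cell average of exp(sigma (r^2 - a^2)/2) over [a, b] with
# weight r: closed form (exp(S) - 1)/S with S = sigma (b^2 - a^2)/2.
sector_average_factor <- function(sigma, meniscus, base) {
  S <- sigma * (base^2 - meniscus^2) / 2
  ifelse(abs(S) < 1e-8, 1 + S / 2, expm1(S) / S)
}

# Free-unit meniscus concentration enforcing mass conservation:
# sum_n n c_n(r0) A_n = loading. Strictly increasing in c1, so bisection-safe.
solve_reference_c1 <- function(model, cond, run, loading) {
  sig <- reduced_sigma(model, cond, run$speed_rpm)
  A <- sector_average_factor(sig, run$meniscus, run$base)
  n <- model$stoich
  f <- function(c1) sum(n * species_conc(model, c1) * A) - loading
  upper <- loading / A[1] * (1 + 1e-9)  # margin: f is exactly 0 here when
                                        # the free unit is the only species
  if (!is.finite(f(upper)) || f(upper) < 0)
    stop("mass-conservation root not bracketed (pathological sigma)", call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = upper * 1e-14)$root
}

#' Simulate a sedimentation-equilibrium absorbance profile
#'
#' At equilibrium each species settles into an exponential radial profile
#' \eqn{c_i(r) = c_i(r_0) \exp[\sigma_i (r^2 - r_0^2)/2]} with buoyant
#' coefficient \eqn{\sigma_i = M_i (1 - \bar{v}\rho)\omega^2 / (RT)}; the
#' reference (meniscus) concentrations obey mass action and are scaled by an
#' inner root solve so that the sector-shaped cell average
#' \eqn{\int c_{tot}(r)\, r\, dr / \int r\, dr} equals the loading
#' concentration (mass conservation). Absorbance is
#' pathlength x sum of extinction_i x c_i(r) + baseline, with oligomer
#' extinctions strictly proportional to stoichiometry.
#'
#' @param model A [self_assoc_model()] with all Kd values set.
#' @param cond A [solution_conditions()] object.
#' @param run A [rotor_run()] object.
#' @param loading Loading concentration, molar in free-unit units.
#' @param unit_extinction Molar extinction of the free unit at the run's
#'   wavelength, M^-1 cm^-1.
#' @param baseline Additive absorbance offset, AU.
#' @return An `equilibrium_profile`: data frame columns `radius` (cm) and
#'   `absorbance` (AU) plus run metadata attributes.
#' @export
simulate_profile <- function(model, cond, run, loading,
                             unit_extinction = 30000, baseline = 0) {
  stopifnot(inherits(model, "self_assoc_model"), inherits(cond, "solution_conditions"),
            inherits(run, "rotor_run"))
  if (anyNA(model$log10_kd)) stop("model Kd values must be set to simulate", call. = FALSE)
  if (loading < 0) stop("loading must be non-negative", call. = FALSE)
  sig <- reduced_sigma(model, cond, run$speed_rpm)
  c1ref <- if (loading == 0) 0 else solve_reference_c1(model, cond, run, loading)
  cref <- species_conc(model, c1ref)
  ext <- model$stoich * unit_extinction
  r2 <- run$radius^2 - run$meniscus^2
  conc <- sapply(seq_along(cref), function(i) cref[i] * exp(sig[i] * r2 / 2))
  absorbance <- run$pathlength * drop(conc %*% ext) + baseline
  structure(data.frame(radius = run$radius, absorbance = absorbance),
            class = c("equilibrium_profile", "data.frame"),
            run = run, loading = loading, baseline = baseline,
            unit_extinction = unit_extinction, reference_c1 = c1ref)
}

# ---- Global fitting ------------------------------------------------------

# Noise-free species signal (at reference wavelength scale, baseline 0) for
# one profile under the model with Kd's in `theta` (log10).
profile_signal <- function(theta, model, cond, profile) {
  m <- model
  m$log10_kd <- theta
  run <- attr(profile, "run")
  sim <- simulate_profile(m, cond, run, attr(profile, "loading"),
                          unit_extinction = attr(profile, "ref_extinction"),
                          baseline = 0)
  sim$absorbance
}

# Residual sum of squares with baselines and non-reference extinction ratios
# profiled out (conditionally linear given theta).
sedeq_rss <- function(theta, model, cond, profiles, return_fit = FALSE) {
  wl <- vapply(profiles, function(p) attr(p, "run")$wavelength, numeric(1))
  ref_wl <- vapply(profiles, function(p) attr(p, "is_reference"), logical(1))
  sig <- lapply(profiles, function(p)
    tryCatch(profile_signal(theta, model, cond, p), error = function(e) NULL))
  if (any(vapply(sig, is.null, logical(1)))) {
    if (return_fit) return(NULL)
    return(1e30)
  }
  baselines <- numeric(length(profiles))
  ratios <- c()
  rss <- 0
  # reference-wavelength cells: absorbance = signal + baseline
  for (i in which(ref_wl)) {
    y <- profiles[[i]]$absorbance
    baselines[i] <- mean(y - sig[[i]])
    rss <- rss + sum((y - sig[[i]] - baselines[i])^2)
  }
  # each other wavelength shares one extinction ratio across its cells
  for (w in unique(wl[!ref_wl])) {
    idx <- which(!ref_wl & wl == w)
    sxx <- 0; sxy <- 0
    for (i in idx) {
      s <- sig[[i]]; y <- profiles[[i]]$absorbance
      sc <- s - mean(s); yc <- y - mean(y)
      sxx <- sxx + sum(sc^2); sxy <- sxy + sum(sc * yc)
    }
    ratio <- if (sxx > 0) sxy / sxx else 0
    ratios[as.character(w)] <- ratio
    for (i in idx) {
      y <- profiles[[i]]$absorbance
      baselines[i] <- mean(y - ratio * sig[[i]])
      rss <- rss + sum((y - ratio * sig[[i]] - baselines[i])^2)
    }
  }
  if (return_fit) list(rss = rss, baselines = baselines, ratios = ratios) else rss
}

prepare_profiles <- function(profiles, ref_wavelength, ref_extinction) {
  lapply(profiles, function(p) {
    attr(p, "is_reference") <- attr(p, "run")$wavelength == ref_wavelength
    attr(p, "ref_extinction") <- ref_extinction
    p
  })
}

default_start <- function(model, profiles) {
  loading <- mean(vapply(profiles, function(p) attr(p, "loading"), numeric(1)))
  if (model$isodesmic) return(log10(loading))
  log10(loading^(model$stoich[-1] - 1))
}

#' Global fit of a self-association model to equilibrium profiles
#'
#' Fits the log10 dissociation constants of `model` to a set of equilibrium
#' absorbance profiles collected across rotor speeds, loading concentrations
#' and wavelengths, by nonlinear least squares with mass conservation imposed
#' per cell. Per-cell baselines and the extinction ratio of each
#' non-reference wavelength are conditionally linear and are profiled out at
#' every step (variable projection), leaving only the Kd's to the nonlinear
#' optimiser. Three starts spread over +/- 2 log10 units guard against local
#' minima.
#'
#' @param profiles List of `equilibrium_profile` objects (>= 2).
#' @param model A [self_assoc_model()]; its Kd values are ignored and fitted.
#' @param cond A [solution_conditions()] object.
#' @param ref_wavelength Wavelength (nm) whose extinction is known.
#' @param ref_extinction Free-unit molar extinction at `ref_wavelength`.
#' @param start Optional vector of starting log10 Kd values.
#' @return A `sedeq_fit` object: fitted `log10_kd`, `kd`, per-cell
#'   `baselines`, fitted extinction `ratios` by wavelength, `rss`, residual
#'   degrees of freedom `df`, `reduced_chisq` (RSS/df) and a convergence flag.
#' @export
global_fit <- function(profiles, model, cond = solution_conditions(),
                       ref_wavelength = 280, ref_extinction = 30000,
                       start = NULL) {
  stopifnot(inherits(model, "self_assoc_model"))
  if (length(profiles) < 2) stop("need at least 2 profiles for a global fit",
                                 call. = FALSE)
  pf <- prepare_profiles(profiles, ref_wavelength, ref_extinction)
  theta0 <- if (is.null(start)) default_start(model, pf) else start
  obj <- function(th) sedeq_rss(th, model, cond, pf)
  if (length(theta0) == 0) {
    # no association constants to fit (single non-associating species):
    # only the conditionally linear parameters remain
    best <- list(par = numeric(0), objective = obj(numeric(0)), convergence = 0L)
  } else {
    best <- NULL
    for (shift in c(0, 2, -2)) {
      o <- stats::nlminb(theta0 + shift, obj,
                         control = list(rel.tol = 1e-12, eval.max = 500,
                                        iter.max = 300))
      if (is.null(best) || o$objective < best$objective) best <- o
    }
  }
  lin <- sedeq_rss(best$par, model, cond, pf, return_fit = TRUE)
  n_obs <- sum(vapply(pf, nrow, integer(1)))
  n_par <- length(best$par) + length(lin$baselines) + length(lin$ratios)
  df <- n_obs - n_par
  nm <- if (model$isodesmic) "logK_step"
        else as.character(vapply(model$stoich[-1],
                                 function(n) paste0("logK_n", n), character(1)))
  lk <- stats::setNames(best$par, nm)
  structure(list(log10_kd = lk, kd = stats::setNames(10^best$par, sub("logK", "K", nm)),
                 baselines = lin$baselines, ratios = lin$ratios,
                 rss = lin$rss, df = df, n_obs = n_obs,
                 reduced_chisq = lin$rss / df,
                 converged = best$convergence == 0, model = model, cond = cond,
                 ref_wavelength = ref_wavelength, ref_extinction = ref_extinction),
            class = "sedeq_fit")
}

#' @export
print.sedeq_fit <- function(x, ...) {
  cat(sprintf("Global sedimentation-equilibrium fit: model %s\n", x$model$name))
  for (i in seq_along(x$log10_kd))
    cat(sprintf("  %s = %.4f  (Kd = %.4g)\n", names(x$log10_kd)[i],
                x$log10_kd[i], 10^x$log10_kd[i]))
  if (length(x$ratios))
    cat(sprintf("  extinction ratio @%s nm = %.4f\n", names(x$ratios), x$ratios))
  cat(sprintf("  reduced chi^2 = %.4g on %d d.o.f.%s\n", x$reduced_chisq, x$df,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' F-statistic confidence interval by stepwise parameter scanning
#'
#' Fixes one log10 Kd at a series of values above and below the best fit,
#' refits all remaining parameters at each step, and reports the parameter
#' values where the residual sum of squares crosses the F-statistic threshold
#' \eqn{RSS_{crit} = RSS_{best} (1 + F(level; 1, \nu) / \nu)} for the
#' requested confidence level. Intervals may be asymmetric; a scan that
#' reaches its grid bound without crossing is flagged open-ended.
#'
#' @inheritParams global_fit
#' @param fit A converged `sedeq_fit`.
#' @param param Index or name of the log10 Kd to scan.
#' @param level Confidence level, default 0.68.
#' @param step Scan step in log10 units.
#' @param max_steps Maximum steps scanned on each side.
#' @return List with `lower`, `upper` (log10 Kd), `kd_lower`, `kd_upper`,
#'   `open_lower`, `open_upper` flags and the critical RSS.
#' @export
fstat_confidence <- function(profiles, model, cond, fit, param = 1,
                             level = 0.68, step = 0.05, max_steps = 80,
                             ref_wavelength = fit$ref_wavelength,
                             ref_extinction = fit$ref_extinction) {
  if (is.character(param)) param <- match(param, names(fit$log10_kd))
  stopifnot(!is.na(param), param >= 1, param <= length(fit$log10_kd))
  pf <- prepare_profiles(profiles, ref_wavelength, ref_extinction)
  theta_best <- unname(fit$log10_kd)
  nu <- fit$df
  crit <- fit$rss * (1 + stats::qf(level, 1, nu) / nu)
  free <- setdiff(seq_along(theta_best), param)
  rss_at <- function(val) {
    if (!length(free)) {
      th <- theta_best; th[param] <- val
      return(sedeq_rss(th, model, cond, pf))
    }
    obj <- function(sub) {
      th <- theta_best; th[param] <- val; th[free] <- sub
      sedeq_rss(th, model, cond, pf)
    }
    stats::nlminb(theta_best[free], obj,
                  control = list(rel.tol = 1e-10, eval.max = 300))$objective
  }
  scan_side <- function(dir) {
    prev_val <- theta_best[param]
    for (i in seq_len(max_steps)) {
      val <- theta_best[param] + dir * i * step
      rss <- rss_at(val)
      if (rss >= crit) {
        # bisect the bracketing step (RSS is locally quadratic, so plain
        # linear interpolation across a wide step misplaces the crossing)
        lo <- prev_val; hi <- val
        for (b in 1:12) {
          mid <- (lo + hi) / 2
          if (rss_at(mid) >= crit) hi <- mid else lo <- mid
        }
        return(list(bound = (lo + hi) / 2, open = FALSE))
      }
      prev_val <- val
    }
    list(bound = prev_val, open = TRUE)
  }
  lo <- scan_side(-1); up <- scan_side(+1)
  list(lower = lo$bound, upper = up$bound,
       kd_lower = 10^lo$bound, kd_upper = 10^up$bound,
       open_lower = lo$open, open_upper = up$open, rss_crit = crit)
}

#' Fit and rank competing self-association models
#'
#' Fits each candidate model to the same data and ranks by reduced
#' chi-squared, the criterion used to discriminate the cooperative
#' 1-2-4 ladder from stepwise (1-2-3, 1-2-6, 1-2-8) and isodesmic
#' alternatives. Non-convergence of an individual model is recorded, not
#' fatal.
#'
#' @inheritParams global_fit
#' @param models List of [self_assoc_model()] candidates (>= 2).
#' @return A `sedeq_comparison`: data frame `ranking` (model, reduced_chisq,
#'   converged) sorted best-first, plus the full `fits` list.
#' @export
compare_models <- function(profiles, models, cond = solution_conditions(),
                           ref_wavelength = 280, ref_extinction = 30000) {
  stopifnot(length(models) >= 2)
  fits <- lapply(models, function(m)
    tryCatch(global_fit(profiles, m, cond, ref_wavelength, ref_extinction),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "sedeq_fit_failure")))
  ok <- !vapply(fits, inherits, logical(1), "sedeq_fit_failure")
  tab <- data.frame(
    model = vapply(models, function(m) m$name, character(1)),
    reduced_chisq = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "sedeq_fit")) f$reduced_chisq else NA_real_, numeric(1)), NA),
    converged = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "sedeq_fit")) f$converged else FALSE, logical(1)), FALSE))
  ord <- order(tab$reduced_chisq)
  structure(list(ranking = tab[ord, , drop = FALSE], fits = fits[ord]),
            class = "sedeq_comparison")
}

#' @export
print.sedeq_comparison <- function(x, ...) {
  cat("Model comparison (best first):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Read/write equilibrium profiles as tabular text
#'
#' Profiles are exchanged as flat CSV with columns `radius_cm`, `absorbance`,
#' `speed_rpm`, `loading_M`, `wavelength_nm`, `cell_id`.
#'
#' @param profiles List of `equilibrium_profile` objects.
#' @param path CSV file path.
#' @return `write_profiles_csv` returns `path` invisibly;
#'   `read_profiles_csv` returns a list of `equilibrium_profile` objects.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]; run <- attr(p, "run")
    data.frame(radius_cm = p$radius, absorbance = p$absorbance,
               speed_rpm = run$speed_rpm, loading_M = attr(p, "loading"),
               wavelength_nm = run$wavelength, cell_id = i)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @param meniscus,base,pathlength Cell geometry to attach on read (the flat
#'   CSV schema does not carry it).
#' @export
read_profiles_csv <- function(path, meniscus = 6.9, base = 7.15,
                              pathlength = 1.2) {
  tab <- utils::read.csv(path)
  need <- c("radius_cm", "absorbance", "speed_rpm", "loading_M",
            "wavelength_nm", "cell_id")
  if (!all(need %in% names(tab)))
    stop("profile CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(tab, tab$cell_id), function(d) {
    run <- rotor_run(d$speed_rpm[1], meniscus, base, pathlength,
                     wavelength = d$wavelength_nm[1], n_points = nrow(d))
    run$radius <- d$radius_cm
    structure(data.frame(radius = d$radius_cm, absorbance = d$absorbance),
              class = c("equilibrium_profile", "data.frame"),
              run = run, loading = d$loading_M[1], baseline = NA_real_)
  })
}
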