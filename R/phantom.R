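# Synthetic dynamic cardiac PET phantom with known ground-truth FSV.
#
# The bolus first pass in each blood pool is a gamma-variate whose scale is
# solved in closed form so its total integral equals
# dose / (fsv_true x HR/60); inverting the indicator-dilution equation on
# the ideal curve therefore returns fsv_true exactly. Recirculation is
# modelled as delayed, dispersed, attenuated copies of the first pass; the
# myocardium accumulates tracer from the arterial curve with slow washout;
# partial-volume blur and proportional Gaussian noise are optional.

#' Gamma-variate bolus curve
#'
#' `0` for `t <= t0`, `scale * (t - t0)^alpha * exp(-(t - t0)/beta)` after.
#' Total integral is `scale * beta^(alpha+1) * Gamma(alpha+1)`
#' (see [gamma_variate_auc()]); the peak sits at `t0 + alpha * beta`.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param t0 Bolus arrival time in seconds.
#' @param alpha Shape parameter (>= 0); `alpha = 0` is a pure exponential.
#' @param beta Time constant in seconds (> 0).
#' @param scale Amplitude in Bq/mL/s^alpha.
#' @return Activity concentration in Bq/mL.
#' @export
gamma_variate <- function(t, t0, alpha, beta, scale = 1) {
  if (beta <= 0) stop("beta must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- scale * dt[pos]^alpha * exp(-dt[pos] / beta)
  out
}

#' Closed-form integral of a gamma-variate curve
#' @inheritParams gamma_variate
#' @return `scale * beta^(alpha+1) * Gamma(alpha+1)`, the integral over
#'   `(t0, Inf)`.
#' @export
gamma_variate_auc <- function(alpha, beta, scale = 1) {
  if (beta <= 0) stop("beta must be > 0")
  scale * beta^(alpha + 1) * gamma(alpha + 1)
}

#' Phantom configuration
#'
#' Defaults emulate the acquisition conditions of a 400 MBq bolus
#' (5-10 mL at 1 mL/s, so a roughly 10 s wide first-pass peak: gamma-variate
#' alpha 3, beta 2.5 s), the 27-min 29-frame acetate framing, a venous
#' (right-heart) bolus arrival 8 s and arterial (left-heart) arrival 16 s
#' after injection, and a recirculation fraction of 0.3 returning after
#' 25 s with dispersion 1.8 per pass.
#'
#' @param fsv_true True forward stroke volume in mL.
#' @param heart_rate Heart rate in beats/min.
#' @param dose Injected dose in Bq.
#' @param framing `"acetate_27min"`, `"water_6min"`, or a
#'   [frame_schedule()].
#' @param venous_delay_s,arterial_delay_s Bolus arrival times (s).
#' @param bolus_alpha,bolus_beta Gamma-variate shape and time constant.
#' @param recirculation_fraction Amplitude fraction per recirculation pass,
#'   in `[0, 1)`.
#' @param recirculation_delay_s Delay added per pass (s).
#' @param recirculation_dispersion Widening factor of `beta` per pass.
#' @param n_recirculation_passes Number of recirculation passes.
#' @param myocardial_uptake_rate Uptake constant (1/s) scaling the
#'   arterial-integral myocardial TAC.
#' @param myocardial_washout_rate Myocardial washout constant (1/s).
#' @param psf_fwhm_mm Isotropic Gaussian point-spread FWHM in mm (0 = no
#'   blur).
#' @param noise_sd_fraction Gaussian noise SD as a fraction of each voxel
#'   frame value (0 = noiseless).
#' @param seed Integer seed for noise generation.
#' @param grid_shape Voxel grid `(nx, ny, nz)`.
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @param geometry Compartment geometry, see [phantom_geometry()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(fsv_true = 80, heart_rate = 60, dose = 4e8,
                           framing = "acetate_27min",
                           venous_delay_s = 8, arterial_delay_s = 16,
                           bolus_alpha = 3, bolus_beta = 2.5,
                           recirculation_fraction = 0.3,
                           recirculation_delay_s = 25,
                           recirculation_dispersion = 1.8,
                           n_recirculation_passes = 3L,
                           myocardial_uptake_rate = 0.01,
                           myocardial_washout_rate = 0.002,
                           psf_fwhm_mm = 0, noise_sd_fraction = 0,
                           seed = 1L,
                           grid_shape = c(64L, 64L, 32L), spacing_mm = 3,
                           geometry = NULL) {
  if (fsv_true <= 0 || heart_rate <= 0 || dose <= 0)
    stop("fsv_true, heart_rate and dose must be > 0")
  if (recirculation_fraction < 0 || recirculation_fraction >= 1)
    stop("recirculation_fraction must be in [0, 1)")
  if (venous_delay_s < 0 || arterial_delay_s < 0 || recirculation_delay_s < 0)
    stop("delays must be >= 0")
  if (psf_fwhm_mm < 0 || noise_sd_fraction < 0)
    stop("psf_fwhm_mm and noise_sd_fraction must be >= 0")
  schedule <- if (inherits(framing, "frame_schedule")) framing
    else switch(match.arg(framing, c("acetate_27min", "water_6min")),
                acetate_27min = acetate_framing(), water_6min = water_framing())
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three integers >= 8")
  if (is.null(geometry)) geometry <- phantom_geometry(grid_shape, spacing_mm)
  structure(list(fsv_true = fsv_true, heart_rate = heart_rate, dose = dose,
                 schedule = schedule,
                 venous_delay_s = venous_delay_s,
                 arterial_delay_s = arterial_delay_s,
                 bolus_alpha = bolus_alpha, bolus_beta = bolus_beta,
                 recirculation_fraction = recirculation_fraction,
                 recirculation_delay_s = recirculation_delay_s,
                 recirculation_dispersion = recirculation_dispersion,
                 n_recirculation_passes = as.integer(n_recirculation_passes),
                 myocardial_uptake_rate = myocardial_uptake_rate,
                 myocardial_washout_rate = myocardial_washout_rate,
                 psf_fwhm_mm = psf_fwhm_mm,
                 noise_sd_fraction = noise_sd_fraction,
                 seed = as.integer(seed),
                 grid_shape = grid_shape, spacing_mm = spacing_mm,
                 geometry = geometry),
            class = "phantom_config")
}

#' Default phantom compartment geometry
#'
#' A cylindrical arterial pool (left heart plus aorta, 15 mm radius), a
#' parallel venous cylinder, and an annular myocardium (21-30 mm radii)
#' around the arterial pool, all spanning the central 70% of the z axis.
#' Dimensions are in mm, so the physical phantom is unchanged when the
#' voxel grid is refined or coarsened. Any compartment may be `NULL` to
#' omit it.
#'
#' @param grid_shape Voxel grid `(nx, ny, nz)`.
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @return List of compartments `arterial`, `venous`, `myocardium`, each a
#'   list with `center_frac` (x,y as grid fractions), `radius_mm` (or
#'   `inner_radius_mm`/`outer_radius_mm`), `z_margin_frac`.
#' @export
phantom_geometry <- function(grid_shape, spacing_mm = 3) {
  list(arterial = list(center_frac = c(0.35, 0.5), radius_mm = 15,
                       z_margin_frac = 0.15),
       venous = list(center_frac = c(0.70, 0.5), radius_mm = 15,
                     z_margin_frac = 0.15),
       myocardium = list(center_frac = c(0.35, 0.5),
                         inner_radius_mm = 21, outer_radius_mm = 30,
                         z_margin_frac = 0.15))
}

.cylinder_mask <- function(grid_shape, spacing_mm, center_frac, r_in_mm, r_out_mm,
                           z_margin_frac) {
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  cx <- center_frac[1L] * nx; cy <- center_frac[2L] * ny
  x <- (seq_len(nx) - 0.5 - cx) * spacing_mm
  y <- (seq_len(ny) - 0.5 - cy) * spacing_mm
  r2 <- outer(x^2, y^2, "+")
  disc <- r2 > r_in_mm^2 & r2 <= r_out_mm^2
  z0 <- max(1L, ceiling(z_margin_frac * nz))
  z1 <- min(nz, nz - z0 + 1L)
  zok <- seq_len(nz) >= z0 & seq_len(nz) <= z1
  array(disc, dim = grid_shape) & rep(zok, each = nx * ny)
}

.phantom_masks <- function(config) {
  g <- config$geometry
  mk <- function(cp) {
    if (is.null(cp)) return(NULL)
    r_in <- if (!is.null(cp$inner_radius_mm)) cp$inner_radius_mm else -1
    r_out <- if (!is.null(cp$outer_radius_mm)) cp$outer_radius_mm else cp$radius_mm
    .cylinder_mask(config$grid_shape, config$spacing_mm, cp$center_frac,
                   r_in, r_out, cp$z_margin_frac)
  }
  masks <- Filter(Negate(is.null),
                  list(arterial = mk(g$arterial), venous = mk(g$venous),
                       myocardium = mk(g$myocardium)))
  if (length(masks) >= 2L) {
    tot <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), dim(m))))
    if (any(tot > 1L)) stop("phantom compartments overlap")
  }
  masks
}

#' Ideal blood-pool TACs for a phantom configuration
#'
#' The first pass of each pool is a gamma-variate with total integral
#' `dose / (fsv_true x HR/60)` (identical for venous and arterial: mass
#' conservation through the circuit in series, only the arrival delay
#' differs). Recirculation pass `k` is delayed by `k x recirculation_delay_s`,
#' carries `recirculation_fraction^k` of the first-pass integral, and has
#' its `beta` widened by `recirculation_dispersion^k`.
#'
#' @param config A [phantom_config()].
#' @return List with continuous-time evaluators `arterial(t)`, `venous(t)`,
#'   `arterial_first_pass(t)`, `venous_first_pass(t)`, and
#'   `first_pass_auc` (Bq·s/mL, closed form), `total_auc_factor`
#'   (`sum(frac^k)` over passes).
#' @export
make_blood_tacs <- function(config) {
  target_auc <- config$dose / (config$fsv_true * config$heart_rate / 60)
  a <- config$bolus_alpha; b <- config$bolus_beta
  frac <- config$recirculation_fraction
  npass <- if (frac > 0) config$n_recirculation_passes else 0L
  pass_scale <- function(k) {
    bk <- b * config$recirculation_dispersion^k
    frac^k * target_auc / gamma_variate_auc(a, bk)
  }
  curve <- function(delay) {
    force(delay)
    function(t) {
      out <- numeric(length(t))
      for (k in 0:npass) {
        bk <- b * config$recirculation_dispersion^k
        out <- out + gamma_variate(t, delay + k * config$recirculation_delay_s,
                                   a, bk, pass_scale(k))
      }
      out
    }
  }
  fp_curve <- function(delay) {
    force(delay)
    function(t) gamma_variate(t, delay, a, b, target_auc / gamma_variate_auc(a, b))
  }
  list(arterial = curve(config$arterial_delay_s),
       venous = curve(config$venous_delay_s),
       arterial_first_pass = fp_curve(config$arterial_delay_s),
       venous_first_pass = fp_curve(config$venous_delay_s),
       first_pass_auc = target_auc,
       total_auc_factor = sum(frac^(0:npass)))
}

# Frame-averaged values of a continuous curve: composite-trapezoid mean
# over each frame window.
.frame_average <- function(f, schedule, n_sub = 100L) {
  vapply(seq_len(n_frames(schedule)), function(j) {
    ts <- seq(schedule$frame_start[j], frame_end(schedule)[j],
              length.out = n_sub + 1L)
    v <- f(ts)
    sum((v[-1L] + v[-length(v)]) / 2) / n_sub
  }, numeric(1))
}

#' Frame-average a continuous TAC over a schedule
#'
#' @param f Continuous-time evaluator `f(t)` in Bq/mL.
#' @param schedule A [frame_schedule()].
#' @param n_sub Trapezoid subdivisions per frame.
#' @return A [tac()] of per-frame mean activity.
#' @export
frame_average_tac <- function(f, schedule, n_sub = 100L) {
  tac(frame_mid(schedule), .frame_average(f, schedule, n_sub), schedule)
}

# Separable 3D Gaussian blur. Kernel columns are renormalized so each
# input voxel redistributes exactly unit mass: per-frame total activity is
# conserved to machine precision.
.gaussian_blur_3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, sd = s)
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      rows <- (j - r):(j + r)
      ok <- rows >= 1L & rows <= n
      K[rows[ok], j] <- k[ok] / sum(k[ok])
    }
    vol <- if (ax == 1L) {
      array(K %*% matrix(vol, d[1L]), d)
    } else if (ax == 2L) {
      array(aperm(array(K %*% matrix(aperm(vol, c(2L, 1L, 3L)), d[2L]),
                        d[c(2L, 1L, 3L)]), c(2L, 1L, 3L)), d)
    } else {
      array(t(K %*% t(matrix(vol, d[1L] * d[2L], d[3L]))), d)
    }
  }
  vol
}

#' Simulate a dynamic PET series with known ground truth
#'
#' Each compartment voxel carries its compartment's continuous TAC
#' frame-averaged over the frame windows; the myocardium receives a
#' cumulative-uptake TAC (uptake rate times the washout-convolved integral
#' of the arterial curve) so clustering faces realistic competition.
#' Optional per-frame 3D Gaussian blur induces partial-volume dilution;
#' optional proportional Gaussian noise is seeded and reproducible
#' (identical seeds give bit-identical series).
#'
#' @param config A [phantom_config()].
#' @return List with `series` (a [dynamic_series()]) and `truth`
#'   (class `phantom_ground_truth`): `fsv_true`, compartment masks, ideal
#'   continuous evaluators, frame-averaged ideal TACs,
#'   `first_pass_auc_true` (= `dose/(fsv_true x HR/60)` by construction)
#'   and the config.
#' @export
simulate_dynamic_series <- function(config = phantom_config()) {
  schedule <- config$schedule
  masks <- .phantom_masks(config)
  if (is.null(masks$arterial) || is.null(masks$venous))
    stop("phantom requires arterial and venous compartments")
  tacs <- make_blood_tacs(config)

  scan_end <- frame_end(schedule)[n_frames(schedule)]
  if (config$arterial_delay_s + config$bolus_alpha * config$bolus_beta > scan_end)
    warning("frame schedule shorter than bolus support")

  comp_curves <- list(arterial = tacs$arterial, venous = tacs$venous)
  if (!is.null(masks$myocardium)) {
    # washout-convolved cumulative uptake on a fine grid
    ft <- seq(0, scan_end, by = 0.1)
    ca <- tacs$arterial(ft)
    kw <- config$myocardial_washout_rate
    dt <- ft[2L] - ft[1L]
    g <- ca * exp(kw * ft)
    cum <- c(0, cumsum((g[-1L] + g[-length(g)]) / 2 * dt))
    myo <- config$myocardial_uptake_rate * exp(-kw * ft) * cum
    comp_curves$myocardium <- stats::approxfun(ft, myo, rule = 2)
  }

  frame_vals <- lapply(comp_curves, .frame_average, schedule = schedule)

  nt <- n_frames(schedule)
  d <- config$grid_shape
  vox <- array(0, dim = c(d, nt))
  plane <- prod(d)
  for (nm in names(frame_vals)) {
    idx <- which(masks[[nm]])
    for (j in seq_len(nt))
      vox[idx + (j - 1L) * plane] <- frame_vals[[nm]][j]
  }

  if (config$psf_fwhm_mm > 0) {
    sigma_vox <- rep(config$psf_fwhm_mm / 2.3548200450309493 / config$spacing_mm, 3L)
    for (j in seq_len(nt)) {
      vol <- array(vox[, , , j], dim = d)
      vox[, , , j] <- .gaussian_blur_3d(vol, sigma_vox)
    }
  }

  if (config$noise_sd_fraction > 0) {
    vox <- .with_seed(config$seed, {
      nz <- which(vox > 0)
      vox[nz] <- vox[nz] + stats::rnorm(length(nz),
                                        sd = config$noise_sd_fraction * vox[nz])
      vox
    })
  }

  series <- dynamic_series(vox, rep(config$spacing_mm, 3L), schedule)
  truth <- structure(list(
    fsv_true = config$fsv_true,
    arterial_mask = masks$arterial, venous_mask = masks$venous,
    myocardial_mask = masks$myocardium,
    ideal_arterial = tacs$arterial, ideal_venous = tacs$venous,
    ideal_arterial_first_pass = tacs$arterial_first_pass,
    ideal_venous_first_pass = tacs$venous_first_pass,
    arterial_tac = tac(frame_mid(schedule), frame_vals$arterial, schedule),
    venous_tac = tac(frame_mid(schedule), frame_vals$venous, schedule),
    first_pass_auc_true = tacs$first_pass_auc,
    config = config), class = "phantom_ground_truth")
  list(series = series, truth = truth)
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf("phantom_ground_truth: FSV %.1f mL, first-pass AUC %.6g Bq*s/mL, %d/%d arterial/venous voxels\n",
              x$fsv_true, x$first_pass_auc_true,
              sum(x$arterial_mask), sum(x$venous_mask)))
  invisible(x)
}
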