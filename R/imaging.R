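#' Modality profile
#'
#' Describes how a detection modality degrades the ground truth: a Gaussian
#' point-spread function (full width at half maximum, micrometres), an output
#' voxel size, and a noise model. `kind` records whether voxel values are
#' tracer activity (PET-like) or Hounsfield units (CT-like), which downstream
#' thresholding checks.
#'
#' @param name Profile label.
#' @param kind `"activity"` or `"hu"`.
#' @param psf_fwhm PSF full width at half maximum, micrometres (>= 0).
#' @param out_voxel_size Output voxel edge, micrometres (> 0).
#' @param noise Noise model: `"none"`, or a list `list(type = "gaussian",
#'   sd = ...)` (additive, in image units) or `list(type = "poisson",
#'   scale = ...)` (counts drawn at `value * scale` then rescaled).
#' @param detection_floor Minimum representable object scale, micrometres
#'   (informational; CT-like only).
#' @return A list of class `modality_profile`.
#' @export
modality_profile <- function(name, kind = c("activity", "hu"),
                             psf_fwhm, out_voxel_size,
                             noise = "none", detection_floor = NA_real_) {
  kind <- match.arg(kind)
  if (!is_scalar_number(psf_fwhm) || psf_fwhm < 0) abort("`psf_fwhm` must be >= 0")
  if (!is_scalar_number(out_voxel_size) || out_voxel_size <= 0) {
    abort("`out_voxel_size` must be > 0")
  }
  if (is.character(noise)) noise <- list(type = match.arg(noise, "none"))
  if (!noise$type %in% c("none", "gaussian", "poisson")) {
    abort("noise type must be none, gaussian or poisson")
  }
  structure(
    list(name = name, kind = kind, psf_fwhm = psf_fwhm,
         out_voxel_size = out_voxel_size, noise = noise,
         detection_floor = detection_floor),
    class = "modality_profile"
  )
}

#' Built-in modality presets
#'
#' Resolution presets used throughout the package: phosphor-screen
#' autoradiography (FWHM 50 um at 25 um pixels), microPET (900 um at 300 um
#' voxels), microCT (30 um at 22 um), clinical PET (4500 um at 2000 um — a
#' conventional figure for the scanner class, not a measured one) and clinical
#' CT (600 um at 500 um). Histology is modelled as an essentially unblurred
#' mineral image at 25 um pixels. Noise defaults: PET-like Poisson, CT-like
#' additive Gaussian of 15 HU; pass `noise = "none"` to disable.
#'
#' @param name One of `"autoradiography"`, `"histology"`, `"micro_pet"`,
#'   `"micro_ct"`, `"clinical_pet"`, `"clinical_ct"`.
#' @param noise Override the preset noise model (see [modality_profile()]).
#' @param out_voxel_size Override the preset output voxel size (micrometres).
#' @return A `modality_profile`.
#' @export
modality_preset <- function(name = c("autoradiography", "histology",
                                     "micro_pet", "micro_ct",
                                     "clinical_pet", "clinical_ct"),
                            noise = NULL, out_voxel_size = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    autoradiography = list(kind = "activity", fwhm = 50, vox = 25,
                           noise = list(type = "poisson", scale = 100),
                           floor = NA_real_),
    histology = list(kind = "hu", fwhm = 5, vox = 25,
                     noise = list(type = "none"), floor = NA_real_),
    micro_pet = list(kind = "activity", fwhm = 900, vox = 300,
                     noise = list(type = "poisson", scale = 100),
                     floor = NA_real_),
    micro_ct = list(kind = "hu", fwhm = 30, vox = 22,
                    noise = list(type = "gaussian", sd = 15), floor = 200),
    clinical_pet = list(kind = "activity", fwhm = 4500, vox = 2000,
                        noise = list(type = "poisson", scale = 100),
                        floor = NA_real_),
    clinical_ct = list(kind = "hu", fwhm = 600, vox = 500,
                       noise = list(type = "gaussian", sd = 15), floor = 500)
  )
  modality_profile(name, kind = p$kind, psf_fwhm = p$fwhm,
                   out_voxel_size = out_voxel_size %||% p$vox,
                   noise = noise %||% p$noise,
                   detection_floor = p$floor)
}

#' Render a ground-truth map through a modality
#'
#' Convolves the truth with the modality's Gaussian point-spread function
#' (sigma = FWHM / 2.3548), block-averages down to the output voxel size (an
#' integer multiple of the input voxel size) and applies the noise model.
#' With no noise, the integrated signal (sum times voxel volume) is conserved
#' exactly.
#'
#' @param truth An `activity_map`, an `image_volume`, or a list with `grid`
#'   and `voxel_size`.
#' @param profile A [modality_profile()].
#' @param seed Integer seed for the noise draw (ignored when noise is none).
#' @return An `image_volume`: list with `grid`, `voxel_size`, `modality`.
#' @export
apply_modality <- function(truth, profile, seed = 1L) {
  stopifnot(inherits(profile, "modality_profile"))
  grid <- truth$grid
  vs <- truth$voxel_size
  if (is.null(grid) || is.null(vs)) abort("`truth` must carry `grid` and `voxel_size`")
  if (profile$out_voxel_size < vs - 1e-9) {
    abort(paste0("output voxel (", profile$out_voxel_size,
                 " um) is finer than the truth grid (", vs, " um)"))
  }
  factor <- profile$out_voxel_size / vs
  if (abs(factor - round(factor)) > 1e-8) {
    abort("`out_voxel_size` must be an integer multiple of the truth voxel size")
  }
  factor <- as.integer(round(factor))
  sigma_vox <- fwhm_to_sigma(profile$psf_fwhm) / vs
  out <- gaussian_blur(grid, sigma_vox)
  if (factor > 1L) out <- block_average(out, factor)
  if (profile$noise$type == "gaussian") {
    withr::with_seed(as.integer(seed), {
      out <- out + rnorm(length(out), 0, profile$noise$sd)
    })
  } else if (profile$noise$type == "poisson") {
    sc <- profile$noise$scale
    withr::with_seed(as.integer(seed), {
      out[] <- rpois(length(out), pmax(out, 0) * sc) / sc
    })
  }
  if (profile$kind == "hu") out <- pmax(out, -1024)
  structure(
    list(grid = out, voxel_size = profile$out_voxel_size, modality = profile),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$grid), collapse = " x "), " @ ",
      x$voxel_size, " um (", x$modality$name, ", ", x$modality$kind, ")\n",
      sep = "")
  invisible(x)
}

#' Map a phantom's mineral content to Hounsfield units
#'
#' Piecewise mapping: background to `hu_bg` (water-equivalent bath), soft
#' tissue to `hu_soft`, and calcified voxels to
#' `hu_soft + mineral_density * (hu_calc - hu_soft)` — monotone in mineral
#' density, and at full density well above the 1,000 HU rule used to define
#' calcification, so that partial volume, not the mapping, governs
#' detectability.
#'
#' @param phantom A `plaque_phantom`.
#' @param hu_bg,hu_soft,hu_calc Hounsfield values for background, soft tissue
#'   and fully dense mineral (defaults 0, 40, 1300).
#' @return A list with `grid` (HU) and `voxel_size`, ready for
#'   [apply_modality()].
#' @export
mineral_to_hu <- function(phantom, hu_bg = 0, hu_soft = 40, hu_calc = 1300) {
  stopifnot(inherits(phantom, "plaque_phantom"))
  grid <- array(hu_bg, dim = dim(phantom$grid))
  grid[phantom$grid == 1L] <- hu_soft
  calc <- phantom$grid == 2L
  if (any(calc)) {
    dens <- phantom$deposits$mineral_density[phantom$deposit_id[calc]]
    grid[calc] <- hu_soft + dens * (hu_calc - hu_soft)
  }
  list(grid = grid, voxel_size = phantom$voxel_size)
}

#' Biexponential plasma model
#'
#' Arterial plasma concentration after bolus injection,
#' `C(t) = A1 * exp(-lambda1 * t) + A2 * exp(-lambda2 * t)`: a fast
#' redistribution phase and a slow renal-elimination phase. The default rates
#' put the 60-minute value at 6% of peak, inside the observed 4-8% band
#' (`lambda2 = -log(0.6) / 60`).
#'
#' @param A1,A2 Phase amplitudes (activity units, >= 0).
#' @param lambda1,lambda2 Phase rates, min^-1, with `lambda1 > lambda2 > 0`.
#' @param plasma_to_blood_ratio Plasma-over-whole-blood concentration ratio.
#' @return A list of class `plasma_model`.
#' @export
plasma_model <- function(A1 = 0.9, A2 = 0.1,
                         lambda1 = 0.25, lambda2 = -log(0.6) / 60,
                         plasma_to_blood_ratio = 1) {
  if (A1 < 0 || A2 < 0) abort("plasma amplitudes must be >= 0")
  if (!(lambda1 > lambda2 && lambda2 > 0)) {
    abort("plasma rates must satisfy lambda1 > lambda2 > 0")
  }
  structure(
    list(A1 = A1, A2 = A2, lambda1 = lambda1, lambda2 = lambda2,
         plasma_to_blood_ratio = plasma_to_blood_ratio),
    class = "plasma_model"
  )
}

plasma_value <- function(model, t) {
  model$A1 * exp(-model$lambda1 * t) + model$A2 * exp(-model$lambda2 * t)
}

# closed-form running integral of the biexponential from 0 to t
plasma_integral <- function(model, t) {
  model$A1 / model$lambda1 * (1 - exp(-model$lambda1 * t)) +
    model$A2 / model$lambda2 * (1 - exp(-model$lambda2 * t))
}

#' Evaluate a plasma model as a time-activity curve
#'
#' @param model A [plasma_model()].
#' @param times Minutes (>= 0).
#' @return Tibble with `time_min`, `value`, `label = "plasma"`.
#' @export
plasma_curve <- function(model, times) {
  stopifnot(inherits(model, "plasma_model"))
  if (any(times < 0)) abort("plasma times must be >= 0")
  tibble(time_min = as.numeric(times), value = plasma_value(model, times),
         label = "plasma")
}

#' Default 28-frame dynamic acquisition schedule
#'
#' Twelve 10-second frames, four 30-second frames and twelve 240-second
#' frames, spanning 52 minutes from injection.
#'
#' @return Tibble with `frame_start_s`, `frame_end_s`, `t_mid_min`.
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(10, 12), rep(30, 4), rep(240, 12))
  ends <- cumsum(dur)
  starts <- ends - dur
  tibble(frame_start_s = starts, frame_end_s = ends,
         t_mid_min = (starts + ends) / 2 / 60)
}

#' Simulate a dynamic PET study under irreversible trapping
#'
#' Generates tissue and blood time-activity curves obeying the
#' irreversible-uptake relation
#' `C_t(t) = Ki * integral(C_b, 0, t) + V * C_b(t)`, with the blood curve
#' taken from the biexponential plasma model (divided by the plasma-to-blood
#' ratio) and the running integral evaluated in closed form. Frame values are
#' the model evaluated at the frame midpoint. Optional multiplicative
#' Gaussian noise.
#'
#' @param Ki Net influx constant, ml cm^-3 min^-1 (>= 0).
#' @param V Effective distribution volume (dimensionless).
#' @param plasma A [plasma_model()].
#' @param schedule Frame table with `frame_start_s`, `frame_end_s` (default
#'   [default_frame_schedule()]).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise
#'   applied to both curves (0 = noiseless).
#' @param seed Integer seed for the noise draw.
#' @return Tibble of class `dynamic_study`: `frame_start_s`, `frame_end_s`,
#'   `t_mid_min`, `plasma`, `tissue`.
#' @export
simulate_dynamic_study <- function(Ki, V, plasma = plasma_model(),
                                   schedule = default_frame_schedule(),
                                   noise_cv = 0, seed = 1L) {
  stopifnot(inherits(plasma, "plasma_model"))
  if (!is_scalar_number(Ki) || Ki < 0) abort("`Ki` must be >= 0")
  if (nrow(schedule) == 0) abort("frame schedule is empty")
  if (any(schedule$frame_end_s <= schedule$frame_start_s)) {
    abort("frame durations must be positive")
  }
  a <- schedule$frame_start_s / 60
  b <- schedule$frame_end_s / 60
  t_mid <- (a + b) / 2
  r <- plasma$plasma_to_blood_ratio
  cb <- plasma_value(plasma, t_mid) / r
  tissue <- Ki * plasma_integral(plasma, t_mid) / r + V * cb
  if (noise_cv > 0) {
    withr::with_seed(as.integer(seed), {
      cb <- cb * (1 + rnorm(length(cb), 0, noise_cv))
      tissue <- tissue * (1 + rnorm(length(tissue), 0, noise_cv))
    })
  }
  out <- tibble(
    frame_start_s = schedule$frame_start_s,
    frame_end_s = schedule$frame_end_s,
    t_mid_min = t_mid,
    plasma = cb,
    tissue = tissue
  )
  class(out) <- c("dynamic_study", class(out))
  out
}
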