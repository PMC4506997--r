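# End-to-end synthetic study: phantom -> uptake -> multi-resolution rendering
# -> tri-class quantification, plus the kinetic and dynamic analyses.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

# Otsu-based positive mask that degrades gracefully: a constant image (e.g. a
# phantom with nothing to see) yields an empty mask instead of an error, so
# the tri-class step can report the undefined-denominator condition itself.
safe_otsu_mask <- function(img) {
  if (diff(range(img$grid)) == 0) {
    new_binary_mask(array(FALSE, dim = dim(img$grid)), img$voxel_size,
                    list(method = "otsu", note = "constant image, empty mask"))
  } else {
    thr <- otsu_threshold(img)
    new_binary_mask(img$grid > thr, img$voxel_size,
                    list(method = "otsu", threshold = thr))
  }
}

#' Run the full synthetic study
#'
#' Generates a 2D plaque phantom, simulates surface-restricted tracer uptake
#' on it, renders the bound activity and the mineral (Hounsfield) map through
#' three detection levels — clinical PET/CT, microPET/microCT, and
#' autoradiography/histology — and quantifies each pair with the tri-class
#' PET/CT accounting and Pearson mask correlation. PET-like images are
#' thresholded with Otsu (the autoradiography/histology pair uses the full
#' threshold-blur-rethreshold pipeline to match resolutions, as is done for
#' section data); CT-like images use the >= 1,000 HU calcification rule. The
#' same run also produces the kinetic analyses: one-site association and
#' dissociation fits with derived constants, the log-log calibration, the
#' biexponential plasma fit, and Patlak analysis of a simulated dynamic
#' study. Deterministic given `(config, seed)`.
#'
#' @param config A [default_run_config()] (possibly modified or read from
#'   YAML).
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param out_dir Optional directory; when given, every intermediate product
#'   and the resolved configuration are written there.
#' @return A list bundle: `phantom`, `activity`, `images` (per pair),
#'   `masks`, `tri_class` (tibble over pairs), `pearson`, `transect`,
#'   `kinetics` (fits and derived constants), `patlak`, `plasma_fit`, and
#'   `summary` (one tidy tibble of headline numbers).
#' @export
run_end_to_end <- function(config = default_run_config(), seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  check_config_keys(config, default_run_config())

  phantom <- with_stage("phantom", {
    pc <- do.call(phantom_config, config$phantom)
    generate_phantom(pc, seed = child_seed(seed, "phantom"))
  })

  params <- with_stage("adsorption", do.call(
    kinetic_parameters,
    config$adsorption[c("k_on", "k_off", "ligand_conc", "site_density")]
  ))
  activity <- with_stage("adsorption", simulate_uptake(
    phantom, params,
    incubation_time = config$adsorption$incubation_time,
    penetration_depth = config$adsorption$penetration_depth,
    sectioned_first = config$adsorption$sectioned_first,
    binding = config$adsorption$binding
  ))

  hu_truth <- with_stage("imaging", mineral_to_hu(
    phantom, hu_bg = config$imaging$hu_bg, hu_soft = config$imaging$hu_soft,
    hu_calc = config$imaging$hu_calc
  ))

  noise_off <- if (isTRUE(config$imaging$noise)) NULL else "none"
  vs <- phantom$voxel_size
  snap <- function(v) max(vs, round(v / vs) * vs)
  pairs <- list(
    clinical = list(
      pet = modality_preset("clinical_pet", noise = noise_off,
                            out_voxel_size = snap(500)),
      ct = modality_preset("clinical_ct", noise = noise_off,
                           out_voxel_size = snap(500))
    ),
    micro = list(
      pet = modality_preset("micro_pet", noise = noise_off,
                            out_voxel_size = snap(300)),
      ct = modality_preset("micro_ct", noise = noise_off,
                           out_voxel_size = snap(300))
    ),
    autoradiography = list(
      pet = modality_preset("autoradiography", noise = noise_off,
                            out_voxel_size = snap(25)),
      ct = modality_preset("histology", noise = noise_off,
                           out_voxel_size = snap(25))
    )
  )

  images <- masks <- list()
  tri <- list()
  pearson <- list()
  for (nm in names(pairs)) {
    images[[nm]] <- with_stage(paste0("imaging (", nm, ")"), list(
      pet = apply_modality(activity, pairs[[nm]]$pet,
                           seed = child_seed(seed, paste0(nm, "_pet"))),
      ct = apply_modality(hu_truth, pairs[[nm]]$ct,
                          seed = child_seed(seed, paste0(nm, "_ct")))
    ))
    masks[[nm]] <- with_stage(paste0("quantification (", nm, ")"), {
      if (nm == "autoradiography") {
        pet_m <- if (diff(range(images[[nm]]$pet$grid)) == 0) {
          new_binary_mask(array(FALSE, dim = dim(images[[nm]]$pet$grid)),
                          images[[nm]]$pet$voxel_size,
                          list(method = "pipeline", note = "constant image"))
        } else {
          mask_pipeline(images[[nm]]$pet, "otsu",
                        blur_sigma = config$quantification$blur_sigma, "li")
        }
        ct_m <- if (diff(range(images[[nm]]$ct$grid)) == 0) {
          new_binary_mask(array(FALSE, dim = dim(images[[nm]]$ct$grid)),
                          images[[nm]]$ct$voxel_size,
                          list(method = "pipeline", note = "constant image"))
        } else {
          mask_pipeline(images[[nm]]$ct, "otsu",
                        blur_sigma = config$quantification$blur_sigma, "li")
        }
        list(pet = pet_m, ct = ct_m)
      } else {
        list(pet = safe_otsu_mask(images[[nm]]$pet),
             ct = hu_calcification_mask(images[[nm]]$ct,
                                        config$quantification$hu_threshold))
      }
    })
    tri[[nm]] <- with_stage(paste0("quantification (", nm, ")"),
                            tri_class(masks[[nm]]$pet, masks[[nm]]$ct))
    pearson[[nm]] <- tryCatch(pearson_masks(masks[[nm]]$pet, masks[[nm]]$ct),
                              error = function(e) NA_real_)
  }

  tri_tbl <- dplyr::bind_rows(
    lapply(names(tri), function(nm) dplyr::mutate(as_tibble(tri[[nm]]), pair = nm))
  )
  tri_tbl <- tri_tbl[, c("pair", "class", "count", "percentage")]

  # transect across the largest macro deposit (micro pair), if one exists
  transect <- NULL
  macro <- phantom$deposits[phantom$deposits$class == "macro", ]
  if (nrow(macro) > 0) {
    big <- macro[which.max(macro$radius), ]
    ext <- dim(images$micro$pet$grid) * images$micro$pet$voxel_size
    y0 <- min(max(big$cy, 1), ext[2] - 1)
    transect <- with_stage("quantification (transect)", transect_profile(
      images$micro$pet, images$micro$ct,
      start = c(0.5, y0), end = c(ext[1] - 0.5, y0), n_samples = 256
    ))
  }

  kin <- with_stage("kinetics", {
    kc <- config$kinetics
    assoc_tac <- association_timecourse(params, kc$assoc_times)
    assoc_fit <- fit_association(assoc_tac, params$ligand_conc,
                                 k_off_known = params$k_off)
    wash0 <- association_timecourse(params, config$adsorption$incubation_time)$bound
    diss_tac <- dissociation_timecourse(params, wash0, kc$wash_times)
    diss_fit <- fit_dissociation(diss_tac)
    kd <- derive_kd(assoc_fit$derived$k_on, diss_fit$derived$k_off)
    calib_data <- tibble(
      conc = kc$calib_concs,
      activity = vapply(kc$calib_concs, function(L) {
        p <- kinetic_parameters(params$k_on, params$k_off, L, params$site_density)
        p$site_density * L * (1 - exp(-k_obs(p) * config$adsorption$incubation_time))
      }, numeric(1))
    )
    calib_fit <- fit_concentration_response(calib_data)
    list(association = assoc_fit, dissociation = diss_fit, kd = kd,
         calibration = calib_fit)
  })

  dyn <- with_stage("dynamic", {
    kc <- config$kinetics
    study <- simulate_dynamic_study(kc$Ki, kc$V, plasma_model(),
                                    noise_cv = 0)
    pk <- patlak(study, t_start = kc$t_start)
    pl_tac <- plasma_curve(plasma_model(), seq(0.5, 60, by = 0.5))
    pf <- fit_plasma_biexponential(pl_tac)
    list(study = study, patlak = pk, plasma_fit = pf)
  })

  summary <- tibble(
    quantity = c(
      paste0("pet_only_pct_", tri_tbl$pair[tri_tbl$class == "pet_only"]),
      "k_obs_min^-1", "k_on_M^-1min^-1", "k_off_min^-1", "kd_pm",
      "assoc_half_time_min", "dissoc_half_time_min",
      "calibration_slope", "patlak_ki", "patlak_v",
      "plasma_60min_over_peak"
    ),
    value = c(
      tri_tbl$percentage[tri_tbl$class == "pet_only"],
      kin$association$derived$k_obs, kin$association$derived$k_on,
      kin$dissociation$derived$k_off, kin$kd$kd_pm,
      kin$association$derived$half_time, kin$dissociation$derived$half_time,
      kin$calibration$slope, dyn$patlak$Ki, dyn$patlak$V,
      glance(dyn$plasma_fit)$value_60min_over_peak
    )
  )

  bundle <- list(
    phantom = phantom, activity = activity, images = images, masks = masks,
    tri_class = tri_tbl, pearson = unlist(pearson), transect = transect,
    kinetics = kin, dynamic = dyn, summary = summary,
    config = config, seed = seed
  )

  if (!is.null(out_dir)) {
    with_stage("output", write_bundle(bundle, out_dir))
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(bundle$config, file.path(out_dir, "config.yaml"))
  write_phantom(bundle$phantom, file.path(out_dir, "phantom"))
  write_volume(bundle$activity, file.path(out_dir, "activity.nii.gz"))
  for (nm in names(bundle$images)) {
    for (ch in c("pet", "ct")) {
      img <- bundle$images[[nm]][[ch]]
      if (length(dim(img$grid)) == 2) {
        write_section_tiff(img, file.path(out_dir, paste0(nm, "_", ch, ".tiff")))
      } else {
        write_volume(img, file.path(out_dir, paste0(nm, "_", ch, ".nii.gz")))
      }
    }
  }
  readr::write_csv(bundle$tri_class, file.path(out_dir, "tri_class.csv"))
  if (!is.null(bundle$transect)) {
    readr::write_csv(bundle$transect, file.path(out_dir, "transect.csv"))
  }
  readr::write_csv(bundle$dynamic$study, file.path(out_dir, "dynamic_study.csv"))
  readr::write_csv(bundle$summary, file.path(out_dir, "summary.csv"))
  fits <- list(
    association = glance(bundle$kinetics$association),
    dissociation = glance(bundle$kinetics$dissociation),
    kd = bundle$kinetics$kd,
    calibration = glance(bundle$kinetics$calibration),
    patlak = glance(bundle$dynamic$patlak),
    plasma = glance(bundle$dynamic$plasma_fit)
  )
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}
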