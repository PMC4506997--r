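#' Phantom generation parameters
#'
#' Collects the geometry of a synthetic carotid-plaque phantom: a rectangular
#' block of soft tissue seeded with spherical (2D: disc) calcific deposits.
#' Deposits follow the field's size convention: *micro*calcification has a
#' diameter below 50 micrometres, *macro*calcification a diameter of 50
#' micrometres or more, so micro radii must lie in (0, 25) and macro radii in
#' [25, Inf) micrometres.
#'
#' @param domain_size Numeric vector of 2 or 3 physical extents in micrometres.
#' @param voxel_size Isotropic voxel edge in micrometres. Must not exceed the
#'   smallest requested micro radius, so every deposit is resolved.
#' @param n_micro,n_macro Number of micro-/macrocalcific deposits.
#' @param micro_radius_range,macro_radius_range Radius ranges (micrometres)
#'   deposits are drawn from uniformly.
#' @param mineral_density_range Range of relative hydroxyapatite density in
#'   \[0, 1\], drawn uniformly per deposit.
#' @param max_attempts Placement retries per deposit before giving up.
#'
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(domain_size = c(6000, 6000),
                           voxel_size = if (length(domain_size) == 3) 10 else 5,
                           n_micro = 60,
                           n_macro = 3,
                           micro_radius_range = c(8, 20),
                           macro_radius_range = c(150, 600),
                           mineral_density_range = c(1, 1),
                           max_attempts = 1000) {
  if (!length(domain_size) %in% 2:3 || any(domain_size <= 0)) {
    abort("`domain_size` must be 2 or 3 positive extents in micrometres")
  }
  if (!is_scalar_number(voxel_size) || voxel_size <= 0) {
    abort("`voxel_size` must be a positive scalar (micrometres)")
  }
  if (n_micro < 0 || n_macro < 0) abort("deposit counts must be non-negative")
  if (n_micro > 0) {
    if (micro_radius_range[1] <= 0 || micro_radius_range[2] >= 25) {
      abort("micro radii must lie in (0, 25) micrometres (diameter < 50)")
    }
    if (voxel_size > micro_radius_range[1]) {
      abort(paste0(
        "voxel_size (", voxel_size, " um) is too coarse to represent the ",
        "smallest requested micro deposit (radius ", micro_radius_range[1],
        " um); refine the grid or enlarge the deposits"
      ))
    }
  }
  if (n_macro > 0 && macro_radius_range[1] < 25) {
    abort("macro radii must be >= 25 micrometres (diameter >= 50)")
  }
  if (n_macro > 0 && macro_radius_range[2] > min(domain_size) / 2) {
    abort("largest macro radius does not fit inside the domain")
  }
  structure(
    list(
      domain_size = as.numeric(domain_size),
      voxel_size = as.numeric(voxel_size),
      n_micro = as.integer(n_micro),
      n_macro = as.integer(n_macro),
      micro_radius_range = as.numeric(micro_radius_range),
      macro_radius_range = as.numeric(macro_radius_range),
      mineral_density_range = as.numeric(mineral_density_range),
      max_attempts = as.integer(max_attempts)
    ),
    class = "phantom_config"
  )
}

#' Classify calcific deposits by the 50-micrometre diameter convention
#'
#' Deposits with diameter below 50 micrometres are microcalcification; 50
#' micrometres or more is macrocalcification (the boundary is inclusive on the
#' macro side).
#'
#' @param radius Numeric vector of deposit radii in micrometres.
#' @return Character vector, `"micro"` or `"macro"`.
#' @examples
#' classify_deposit(c(24.5, 25))
#' @export
classify_deposit <- function(radius) {
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius <= 0)) {
    abort("deposit radius must be positive and finite")
  }
  ifelse(2 * radius < 50, "micro", "macro")
}

#' Generate a synthetic plaque phantom
#'
#' Places non-overlapping spherical (2D: disc) calcific deposits uniformly at
#' random in a soft-tissue block and rasterizes them onto a label grid
#' (0 = background, 1 = soft tissue, 2 = calcified). A voxel is calcified when
#' its centre lies inside a deposit. The same `(config, seed)` pair always
#' yields the same phantom; the caller's RNG state is untouched.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for deposit placement.
#' @return An object of class `plaque_phantom`: list with `grid` (integer label
#'   array), `deposit_id` (integer array, 0 where none), `voxel_size`
#'   (micrometres), `deposits` (tibble: id, class, radius, mineral_density and
#'   centre coordinates in micrometres) and `dimensionality`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  nd <- length(config$domain_size)
  dims <- as.integer(round(config$domain_size / config$voxel_size))
  if (any(dims < 1)) abort("domain smaller than one voxel")

  withr::local_seed(as.integer(seed))
  specs <- list()
  if (config$n_macro > 0) {
    for (i in seq_len(config$n_macro)) {
      specs[[length(specs) + 1L]] <- list(class = "macro", i = i,
        range = config$macro_radius_range)
    }
  }
  if (config$n_micro > 0) {
    for (i in seq_len(config$n_micro)) {
      specs[[length(specs) + 1L]] <- list(class = "micro", i = i,
        range = config$micro_radius_range)
    }
  }

  centers <- matrix(numeric(0), ncol = nd)
  radii <- numeric(0)
  classes <- character(0)
  dens <- numeric(0)
  for (sp in specs) {
    r <- runif(1, sp$range[1], sp$range[2])
    placed <- FALSE
    for (attempt in seq_len(config$max_attempts)) {
      ctr <- vapply(seq_len(nd), function(d) {
        runif(1, r, config$domain_size[d] - r)
      }, numeric(1))
      ok <- TRUE
      if (length(radii)) {
        d2 <- colSums((t(centers) - ctr)^2)
        ok <- all(d2 > (radii + r)^2)
      }
      if (ok) {
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
        classes <- c(classes, sp$class)
        dens <- c(dens, runif(1, config$mineral_density_range[1],
                              config$mineral_density_range[2]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0("could not place ", sp$class, " deposit ", sp$i, " (radius ",
                   signif(r, 4), " um) after ", config$max_attempts,
                   " attempts; reduce counts or radii"))
    }
  }

  grid <- array(1L, dim = dims)
  deposit_id <- array(0L, dim = dims)
  vs <- config$voxel_size
  axes <- lapply(dims, function(n) (seq_len(n) - 0.5) * vs)
  for (j in seq_along(radii)) {
    ctr <- centers[j, ]
    r <- radii[j]
    rng <- lapply(seq_len(nd), function(d) {
      lo <- max(1L, floor((ctr[d] - r) / vs - 0.5) + 1L)
      hi <- min(dims[d], ceiling((ctr[d] + r) / vs + 0.5))
      lo:hi
    })
    coords <- lapply(seq_len(nd), function(d) axes[[d]][rng[[d]]] - ctr[d])
    if (nd == 2L) {
      d2 <- outer(coords[[1]]^2, coords[[2]]^2, `+`)
      inside <- d2 <= r^2
      sub <- grid[rng[[1]], rng[[2]], drop = FALSE]
      sub[inside] <- 2L
      grid[rng[[1]], rng[[2]]] <- sub
      sid <- deposit_id[rng[[1]], rng[[2]], drop = FALSE]
      sid[inside] <- j
      deposit_id[rng[[1]], rng[[2]]] <- sid
    } else {
      d2 <- outer(outer(coords[[1]]^2, coords[[2]]^2, `+`), coords[[3]]^2, `+`)
      inside <- d2 <= r^2
      sub <- grid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      sub[inside] <- 2L
      grid[rng[[1]], rng[[2]], rng[[3]]] <- sub
      sid <- deposit_id[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      sid[inside] <- j
      deposit_id[rng[[1]], rng[[2]], rng[[3]]] <- sid
    }
  }

  deposits <- tibble(
    id = seq_along(radii),
    class = classes,
    radius = radii,
    mineral_density = dens
  )
  cn <- c("cx", "cy", "cz")[seq_len(nd)]
  for (d in seq_len(nd)) deposits[[cn[d]]] <- centers[, d]

  structure(
    list(grid = grid, deposit_id = deposit_id, voxel_size = vs,
         deposits = deposits, dimensionality = nd,
         domain_size = config$domain_size),
    class = "plaque_phantom"
  )
}

#' @export
print.plaque_phantom <- function(x, ...) {
  cat("<plaque_phantom> ", paste(dim(x$grid), collapse = " x "),
      " voxels @ ", x$voxel_size, " um\n", sep = "")
  cat("  deposits: ", sum(x$deposits$class == "micro"), " micro, ",
      sum(x$deposits$class == "macro"), " macro; calcified voxels: ",
      sum(x$grid == 2L), "\n", sep = "")
  invisible(x)
}

# Euclidean distance (micrometres) of every voxel to the nearest non-calcified
# voxel centre, computed with an exact distance transform.
calcified_depth_map <- function(phantom) {
  mask <- as.integer(phantom$grid == 2L)
  d2 <- edt_squared(mask, as.integer(dim(phantom$grid)))
  sqrt(d2) * phantom$voxel_size
}

#' Accessible surface shell of a deposit
#'
#' Returns the voxels of one deposit lying within `depth` micrometres
#' (Euclidean distance, via an exact distance transform) of non-calcified
#' tissue — the shell a surface-adsorbing tracer can reach when the tissue is
#' intact. When `depth` is at least the deposit radius the whole deposit is
#' accessible.
#'
#' @param phantom A `plaque_phantom`.
#' @param deposit_id Integer id of a deposit in `phantom$deposits`.
#' @param depth Penetration depth in micrometres (> 0).
#' @return Logical array with the phantom's dimensions.
#' @export
surface_shell <- function(phantom, deposit_id, depth) {
  stopifnot(inherits(phantom, "plaque_phantom"))
  if (!is_scalar_number(depth) || depth <= 0) {
    abort("`depth` must be a positive distance in micrometres")
  }
  dep <- phantom$deposits[phantom$deposits$id == deposit_id, ]
  if (nrow(dep) != 1L) {
    abort(paste0("deposit ", deposit_id, " is not present in this phantom"))
  }
  own <- phantom$deposit_id == deposit_id
  if (depth >= dep$radius) return(own)
  dist <- calcified_depth_map(phantom)
  own & dist <= depth
}

#' Cut a 3D phantom into serial sections
#'
#' Partitions the volume into slabs of the given thickness along one axis, the
#' digital analogue of serial cryosectioning. Sections tile the volume without
#' overlap, so calcified voxels are conserved exactly. Each section records,
#' in attribute `exposed_deposits`, the ids of deposits whose interior is newly
#' exposed at its cut faces (deposits the cutting plane passes through).
#'
#' @param phantom A 3D `plaque_phantom`.
#' @param thickness Section thickness in micrometres; a positive integer
#'   multiple of the voxel size.
#' @param axis Axis to cut along (1, 2 or 3; default 3).
#' @return List of `plaque_phantom` sections in cutting order.
#' @export
section_phantom <- function(phantom, thickness, axis = 3L) {
  stopifnot(inherits(phantom, "plaque_phantom"))
  if (phantom$dimensionality != 3L) abort("section_phantom requires a 3D phantom")
  vs <- phantom$voxel_size
  if (!is_scalar_number(thickness) || thickness < vs) {
    abort("`thickness` must be at least one voxel")
  }
  nvox <- thickness / vs
  if (abs(nvox - round(nvox)) > 1e-8) {
    abort("`thickness` must be an integer multiple of the voxel size")
  }
  nvox <- as.integer(round(nvox))
  n <- dim(phantom$grid)[axis]
  starts <- seq(1L, n, by = nvox)
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:min(starts[k] + nvox - 1L, n)
    sel <- list(TRUE, TRUE, TRUE)
    sel[[axis]] <- idx
    sub <- do.call(`[`, c(list(phantom$grid), sel, list(drop = FALSE)))
    sid <- do.call(`[`, c(list(phantom$deposit_id), sel, list(drop = FALSE)))
    ids_here <- setdiff(unique(as.vector(sid)), 0L)
    # a deposit is cut open when it also extends beyond this slab
    outside <- phantom$deposit_id
    outside_sel <- sel
    outside_sel[[axis]] <- setdiff(seq_len(n), idx)
    out_ids <- if (length(outside_sel[[axis]])) {
      setdiff(unique(as.vector(
        do.call(`[`, c(list(outside), outside_sel, list(drop = FALSE)))
      )), 0L)
    } else integer(0)
    exposed <- intersect(ids_here, out_ids)
    drop2d <- dim(sub)[axis] == 1L
    if (drop2d) {
      sub <- array(sub, dim = dim(sub)[-axis])
      sid <- array(sid, dim = dim(sid)[-axis])
    }
    sec <- structure(
      list(grid = sub, deposit_id = sid, voxel_size = vs,
           deposits = phantom$deposits[phantom$deposits$id %in% ids_here, ],
           dimensionality = if (drop2d) 2L else 3L,
           domain_size = dim(sub) * vs),
      class = "plaque_phantom"
    )
    attr(sec, "exposed_deposits") <- exposed
    attr(sec, "section_index") <- k
    sec
  })
}
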