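grid_of <- function(image) {
  if (is.list(image) && !is.null(image$grid)) image$grid else image
}

#' Otsu automatic threshold
#'
#' Histogram-based threshold maximizing the between-class variance. Values are
#' binned into `n_bins` equal-width bins over their range (continuous data are
#' thereby min-max scaled, matching common practice); the returned threshold
#' is the upper edge of the background bin, so the positive class is
#' `value > threshold`. Ties are broken toward the lowest qualifying
#' threshold.
#'
#' @param image Numeric vector, matrix or array (or an `image_volume`).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value, on the scale of the input.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(grid_of(image))
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) abort("cannot threshold a constant image (one class only)")
  integer_levels <- all(x == round(x)) && diff(rng) < n_bins
  if (integer_levels) {
    # quantized (8/16-bit-like) data: one bin per gray level, so the
    # histogram optimum coincides with the exact-value optimum
    n_bins <- as.integer(diff(rng) + 1)
    w <- 1
  } else {
    w <- diff(rng) / n_bins
  }
  bin <- pmin(floor((x - rng[1]) / w) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * w
  n <- length(x)
  w0 <- cumsum(counts) / n
  sum0 <- cumsum(counts * mids)
  mu_tot <- sum0[n_bins] / n
  # between-class variance for a cut after bin k
  k <- seq_len(n_bins - 1L)
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- sum0[k] / (w0k * n)
  mu1 <- (mu_tot - w0k * mu0) / (1 - w0k)
  bcv[valid] <- (w0k * (1 - w0k) * (mu0 - mu1)^2)[valid]
  best <- which.max(bcv)
  # upper edge of the background bin; for integer levels the edge sits
  # half-way between gray values so the partition is unambiguous
  rng[1] + best * w - if (integer_levels) 0.5 else 0
}

#' Li minimum-cross-entropy threshold
#'
#' Iterative threshold of Li and Tam: starting from the image mean, the next
#' threshold is `(m_b - m_f) / (log(m_b) - log(m_f))` where `m_b`, `m_f` are
#' the means of the two classes under the current threshold; iteration stops
#' when the change falls below `tol`, then snaps to the exact cross-entropy
#' minimizer within one histogram bin of the fixed point. Minimizes the cross
#' entropy between the image and its two-level reconstruction. Requires
#' non-negative values (a tiny offset guards against all-zero class means).
#' Positive class is `value > threshold`.
#'
#' @param image Numeric vector, matrix or array (or an `image_volume`).
#' @param tol Convergence tolerance on the threshold (default: 1e-4 of the
#'   value range).
#' @param max_iter Maximum iterations before failing.
#' @return The threshold value.
#' @export
li_threshold <- function(image, tol = NULL, max_iter = 100L) {
  x <- as.numeric(grid_of(image))
  x <- x[is.finite(x)]
  if (any(x < 0)) abort("Li thresholding requires non-negative values")
  rng <- range(x)
  if (diff(rng) == 0) abort("cannot threshold a constant image (one class only)")
  tol <- tol %||% (diff(rng) * 1e-4)
  eps <- diff(rng) * 1e-9 + 1e-300
  t_cur <- mean(x)
  trace <- t_cur
  for (i in seq_len(max_iter)) {
    m_b <- mean(x[x <= t_cur])
    m_f <- mean(x[x > t_cur])
    if (!is.finite(m_b)) m_b <- rng[1]
    if (!is.finite(m_f)) m_f <- rng[2]
    m_b <- max(m_b, eps)
    m_f <- max(m_f, eps)
    t_new <- if (abs(m_b - m_f) < eps) t_cur else {
      (m_b - m_f) / (log(m_b) - log(m_f))
    }
    trace <- c(trace, t_new)
    if (abs(t_new - t_cur) < tol) {
      return(li_polish(x, t_new, diff(rng) / 256, eps))
    }
    t_cur <- t_new
  }
  abort(paste0("Li threshold did not converge in ", max_iter,
               " iterations; trace: ", paste(signif(trace, 6), collapse = " -> ")))
}

# After the Li-Tam iteration converges, snap to the exact cross-entropy
# minimizer among cut points within one histogram bin of the fixed point
# (the fixed point of the continuous criterion can sit a fraction of a gray
# level away from the discrete optimum).
li_polish <- function(x, t0, bin, eps) {
  u <- sort(unique(x))
  cuts <- (u[-length(u)] + u[-1]) / 2
  cand <- unique(c(t0, cuts[abs(cuts - t0) <= 2 * bin]))
  if (length(cand) == 1L) return(t0)
  score <- vapply(cand, function(tt) {
    b <- x <= tt
    if (!any(b) || all(b)) return(-Inf)
    sum(x[b]) * log(max(mean(x[b]), eps)) +
      sum(x[!b]) * log(max(mean(x[!b]), eps))
  }, numeric(1))
  cand[which.max(score)]
}

new_binary_mask <- function(mask, voxel_size, provenance) {
  structure(list(mask = mask, voxel_size = voxel_size, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$mask), collapse = " x "), "; positive: ",
      sum(x$mask), " (", signif(100 * mean(x$mask), 3), "%)\n", sep = "")
  cat("  provenance: ", paste(unlist(x$provenance), collapse = ", "), "\n", sep = "")
  invisible(x)
}

apply_threshold_method <- function(x, method) {
  if (is.list(method) && identical(method$type, "manual")) {
    list(threshold = method$level, label = paste0("manual(", method$level, ")"))
  } else if (identical(method, "otsu")) {
    list(threshold = otsu_threshold(x), label = "otsu")
  } else if (identical(method, "li")) {
    list(threshold = li_threshold(x), label = "li")
  } else {
    abort("threshold method must be \"otsu\", \"li\" or list(type = \"manual\", level = ...)")
  }
}

#' Threshold / blur / re-threshold segmentation pipeline
#'
#' The two-stage mask construction used to compare signals of different
#' native resolution: binarize with a first automatic (or manual) threshold,
#' smooth the binary field with a Gaussian of `blur_sigma` pixels, and
#' re-binarize with a second automatic threshold. The blurred intermediate is
#' quantized to 256 levels of \[0, 1\] (the 8-bit behaviour of the imaging
#' tools this procedure is modelled on), so features too small to survive the
#' smoothing vanish: if nothing survives, the mask is empty. With
#' `blur_sigma = 0` the result is exactly the single-threshold mask.
#'
#' @param image Numeric matrix/array or `image_volume`.
#' @param first_threshold `"otsu"`, `"li"`, or `list(type = "manual",
#'   level = ...)`.
#' @param blur_sigma Gaussian sigma in pixels of the analysed image
#'   (default 20).
#' @param second_threshold `"li"` (default) or `"otsu"`.
#' @return A `binary_mask` with full provenance.
#' @export
mask_pipeline <- function(image, first_threshold = "otsu", blur_sigma = 20,
                          second_threshold = "li") {
  if (blur_sigma < 0) abort("`blur_sigma` must be >= 0")
  x <- grid_of(image)
  vs <- if (is.list(image)) image$voxel_size else NA_real_
  st1 <- apply_threshold_method(x, first_threshold)
  m1 <- x > st1$threshold
  prov <- list(stage1 = st1$label, threshold1 = st1$threshold,
               blur_sigma_px = blur_sigma)
  if (blur_sigma == 0) {
    return(new_binary_mask(m1, vs, c(prov, list(stage2 = "none"))))
  }
  g <- gaussian_blur(array(as.numeric(m1), dim = dim(x)), blur_sigma)
  g <- round(pmin(pmax(g, 0), 1) * 255) / 255
  if (diff(range(g)) == 0) {
    # nothing survived the smoothing
    mask <- array(FALSE, dim = dim(x))
    return(new_binary_mask(mask, vs, c(prov, list(stage2 = "empty"))))
  }
  st2 <- apply_threshold_method(g, second_threshold)
  mask <- g > st2$threshold
  new_binary_mask(mask, vs,
                  c(prov, list(stage2 = st2$label, threshold2 = st2$threshold)))
}

#' Pearson correlation of two binary masks
#'
#' Standard Pearson coefficient over the 0/1 voxel values of two
#' co-registered masks.
#'
#' @param a,b `binary_mask` objects of identical shape, each containing both
#'   classes.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_masks <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$mask), dim(b$mask))) abort("mask shapes differ")
  va <- as.numeric(a$mask)
  vb <- as.numeric(b$mask)
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("each mask must contain both positive and negative voxels")
  }
  cor(va, vb)
}

#' Tri-class PET/CT accounting
#'
#' Partitions the union of positive voxels of a PET-derived and a CT-derived
#' mask into PET+/CT-, PET+/CT+ and PET-/CT+, with percentages over that
#' union (so the three classes sum to 100).
#'
#' @param pet,ct `binary_mask` objects of identical shape and voxel size.
#' @return Tibble of class `tri_class_result` with columns `class`
#'   (`"pet_only"`, `"both"`, `"ct_only"`), `count`, `percentage`.
#' @export
tri_class <- function(pet, ct) {
  stopifnot(inherits(pet, "binary_mask"), inherits(ct, "binary_mask"))
  if (!identical(dim(pet$mask), dim(ct$mask))) abort("mask shapes differ")
  if (!is.na(pet$voxel_size) && !is.na(ct$voxel_size) &&
      pet$voxel_size != ct$voxel_size) {
    abort("masks have different voxel sizes; resample to a common grid first")
  }
  counts <- c(
    pet_only = sum(pet$mask & !ct$mask),
    both = sum(pet$mask & ct$mask),
    ct_only = sum(!pet$mask & ct$mask)
  )
  tot <- sum(counts)
  if (tot == 0) abort("both masks are empty; tri-class percentages are undefined")
  out <- tibble(class = factor(names(counts), levels = names(counts)),
                count = as.integer(unname(counts)),
                percentage = unname(100 * counts / tot))
  class(out) <- c("tri_class_result", class(out))
  out
}

#' Calcification mask from a CT-like volume
#'
#' Voxels at or above `threshold_hu` Hounsfield units (default 1,000, the
#' standard rule for defining calcification on CT) are positive. Refuses
#' PET-like input, whose values are not Hounsfield units.
#'
#' @param ct An `image_volume` of kind `"hu"`.
#' @param threshold_hu Hounsfield threshold (default 1000).
#' @return A `binary_mask`.
#' @export
hu_calcification_mask <- function(ct, threshold_hu = 1000) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$modality$kind != "hu") {
    abort(paste0("volume '", ct$modality$name,
                 "' holds activity, not Hounsfield units"))
  }
  new_binary_mask(ct$grid >= threshold_hu, ct$voxel_size,
                  list(method = "hu", threshold_hu = threshold_hu,
                       rule = ">="))
}

#' Paired PET/CT profile along a linear transect
#'
#' Samples two co-registered volumes by linear interpolation at `n_samples`
#' evenly spaced points along a physical line — the digital analogue of the
#' 5-8 mm transects drawn across plaque to contrast rim and core signal.
#'
#' @param pet,ct `image_volume`s covering the same physical extent (voxel
#'   sizes may differ).
#' @param start,end Physical endpoints in micrometres (length 2 or 3).
#' @param n_samples Number of sample points (>= 2).
#' @return Tibble of class `transect_profile`: `position_mm`, `pet_value`,
#'   `ct_hu`.
#' @export
transect_profile <- function(pet, ct, start, end, n_samples = 200L) {
  stopifnot(inherits(pet, "image_volume"), inherits(ct, "image_volume"))
  if (n_samples < 2) abort("`n_samples` must be >= 2")
  start <- as.numeric(start); end <- as.numeric(end)
  nd <- length(dim(pet$grid))
  if (length(start) != nd || length(end) != nd) {
    abort("transect endpoints must match the volume dimensionality")
  }
  for (vol in list(pet, ct)) {
    ext <- dim(vol$grid) * vol$voxel_size
    if (any(start < 0) || any(end < 0) ||
        any(start > ext[seq_len(nd)]) || any(end > ext[seq_len(nd)])) {
      abort("transect line exits the volume")
    }
  }
  tt <- seq(0, 1, length.out = n_samples)
  pts <- outer(tt, end - start) + matrix(start, n_samples, nd, byrow = TRUE)
  out <- tibble(
    position_mm = tt * sqrt(sum((end - start)^2)) / 1000,
    pet_value = interp_linear(pet$grid, pet$voxel_size, pts),
    ct_hu = interp_linear(ct$grid, ct$voxel_size, pts)
  )
  class(out) <- c("transect_profile", class(out))
  out
}
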