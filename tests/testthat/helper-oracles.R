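# Independent brute-force oracles for the automatic thresholds, and small
# fixture builders. These never call the implementation paths they check.

# Exhaustive Otsu: scan every cut between consecutive distinct values and
# maximize between-class variance computed directly from the pixel values.
otsu_oracle <- function(x) {
  u <- sort(unique(as.numeric(x)))
  cuts <- (u[-length(u)] + u[-1]) / 2
  n <- length(x)
  bcv <- vapply(cuts, function(tt) {
    b <- x <= tt
    w0 <- mean(b)
    (w0 * (1 - w0)) * (mean(x[b]) - mean(x[!b]))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

# Exhaustive minimum cross entropy: minimizing eta(t) is equivalent to
# maximizing S_b*log(mu_b) + S_f*log(mu_f) over the two classes.
li_oracle <- function(x) {
  x <- as.numeric(x)
  u <- sort(unique(x))
  cuts <- (u[-length(u)] + u[-1]) / 2
  eps <- 1e-12
  score <- vapply(cuts, function(tt) {
    b <- x <= tt
    sb <- sum(x[b]); sf <- sum(x[!b])
    sb * log(max(mean(x[b]), eps)) + sf * log(max(mean(x[!b]), eps))
  }, numeric(1))
  cuts[which.max(score)]
}

# A threshold agrees with its oracle when it induces the same partition
# (thresholds inside an empty histogram gap are equivalent) or differs by at
# most one histogram bin.
threshold_matches_oracle <- function(img, thr, oracle_thr, n_bins = 256) {
  bin <- diff(range(img)) / n_bins
  identical(img > thr, img > oracle_thr) || abs(thr - oracle_thr) <= bin + 1e-9
}

# mask wrapper for hand-built logical matrices
as_mask <- function(m) {
  nafads:::new_binary_mask(m, NA_real_, list(method = "fixture"))
}

# single-macro 3D phantom used by several shell/volume checks
single_macro_phantom_3d <- function(radius = 500, voxel = 10, seed = 1) {
  generate_phantom(
    phantom_config(domain_size = rep(2 * radius + 200, 3), voxel_size = voxel,
                   n_micro = 0, n_macro = 1,
                   macro_radius_range = c(radius, radius)),
    seed = seed
  )
}
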