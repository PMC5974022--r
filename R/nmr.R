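# 1D NMR preprocessing: rolling-ball baseline removal, spectral alignment,
# fixed-width bucketing, total-integral and probabilistic quotient
# normalization. The enforced stage order is
#   baseline -> align -> bucket -> total integral -> PQN
# and each matrix-producing stage records its provenance in the
# "normalization" attribute.

# running min / max with edge replication, flat window of 2*radius + 1
roll_extreme <- function(x, radius, fun) {
  n <- length(x)
  padded <- c(rep(x[1], radius), x, rep(x[n], radius))
  w <- 2 * radius + 1
  vapply(seq_len(n), function(i) fun(padded[i:(i + w - 1)]), numeric(1))
}

roll_mean <- function(x, radius) {
  n <- length(x)
  padded <- c(rep(x[1], radius), x, rep(x[n], radius))
  cs <- cumsum(c(0, padded))
  (cs[(2 * radius + 2):(n + 2 * radius + 1)] - cs[1:n]) / (2 * radius + 1)
}

normalize_spectrum <- function(spec) {
  spec <- as_tibble(spec)
  stopifnot(all(c("ppm", "intensity") %in% names(spec)))
  d <- diff(spec$ppm)
  if (length(d) == 0 || !(all(d > 0) || all(d < 0))) {
    abort("ppm must be strictly monotone")
  }
  if (all(d < 0)) spec <- spec[rev(seq_len(nrow(spec))), ]
  spec
}

#' Rolling-ball baseline removal
#'
#' Estimates a slowly varying baseline by morphological opening (grey-scale
#' erosion then dilation with a flat structuring window of
#' `2 * radius_points + 1` grid points) followed by a moving-average
#' smoothing of the same width, and subtracts it from the spectrum. The
#' pre-smoothing baseline never exceeds the signal, so narrow peaks much
#' thinner than the window survive with their area essentially intact.
#'
#' @param spec Spectrum tibble (`ppm`, `intensity`).
#' @param radius_points Half-width of the flat window, in grid points
#'   (default 50).
#' @return Spectrum tibble with the baseline subtracted; the estimated
#'   baseline is attached as attribute `"baseline"`.
#' @export
rolling_ball_baseline <- function(spec, radius_points = 50) {
  spec <- normalize_spectrum(spec)
  if (radius_points < 1) abort("radius_points must be >= 1")
  n <- nrow(spec)
  if (radius_points >= n) abort("radius_points must be smaller than the signal length")
  eroded <- roll_extreme(spec$intensity, radius_points, min)
  opened <- roll_extreme(eroded, radius_points, max)
  baseline <- roll_mean(opened, radius_points)
  out <- tibble(ppm = spec$ppm, intensity = spec$intensity - baseline)
  attr(out, "baseline") <- baseline
  out
}

#' Align spectra to their median reference by rigid ppm shift
#'
#' Shifts each spectrum along the (shared) ppm grid by the integer-grid
#' offset, bounded by `max_shift_ppm`, that maximizes the normalized
#' cross-correlation with the pointwise-median spectrum. Out-shifted edge
#' points are filled with zeros. Shift estimates are invariant to global
#' intensity scaling of a spectrum.
#'
#' @param spectra List of spectrum tibbles on one common ppm grid.
#' @param max_shift_ppm Maximum allowed |shift| in ppm.
#' @return List of aligned spectrum tibbles; the applied shifts (ppm) are
#'   attached as attribute `"shifts"`.
#' @export
align_spectra <- function(spectra, max_shift_ppm = 0.02) {
  spectra <- lapply(spectra, normalize_spectrum)
  grid <- spectra[[1]]$ppm
  same <- vapply(spectra, function(s) isTRUE(all.equal(s$ppm, grid)), logical(1))
  if (!all(same)) abort("spectra must share a common ppm grid")
  step <- median(diff(grid))
  if (max_shift_ppm >= diff(range(grid))) abort("max_shift_ppm exceeds the grid span")
  max_k <- floor(max_shift_ppm / step)
  mat <- vapply(spectra, function(s) s$intensity, numeric(length(grid)))
  ref <- apply(mat, 1, median)
  shift_one <- function(y, k) {
    n <- length(y)
    if (k > 0) c(rep(0, k), y[1:(n - k)])
    else if (k < 0) c(y[(1 - k):n], rep(0, -k))
    else y
  }
  shifts <- integer(ncol(mat))
  out <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    scores <- vapply(-max_k:max_k, function(k) {
      ys <- shift_one(mat[, j], k)
      s <- sd(ys)
      if (s == 0 || sd(ref) == 0) return(-Inf)
      cor(ys, ref)
    }, numeric(1))
    best <- (-max_k:max_k)[which.max(scores)]
    shifts[j] <- best
    out[[j]] <- tibble(ppm = grid, intensity = shift_one(mat[, j], best))
  }
  attr(out, "shifts") <- shifts * step
  out
}

#' Bucket a spectrum into fixed-width ppm windows
#'
#' Integrates the intensity (trapezoidal rule; each grid panel is assigned
#' to the bucket containing its midpoint) over consecutive half-open
#' buckets `[lo, lo + width)` laid over the spectral range. Buckets that
#' overlap any exclusion interval (water resonance, reference region,
#' spectrum extremes) are dropped entirely.
#'
#' @param spec Spectrum tibble.
#' @param width_ppm Bucket width (default 0.02 ppm).
#' @param exclusions List of `c(lo, hi)` ppm intervals to exclude. Defaults
#'   to the conventional water (4.50-5.20 ppm) and TSP (-0.50-0.50 ppm)
#'   regions plus everything outside 0.50-9.00 ppm.
#' @return Tibble with columns `lo_ppm`, `hi_ppm`, `value`.
#' @export
bucket_spectrum <- function(spec, width_ppm = 0.02,
                            exclusions = default_nmr_exclusions()) {
  spec <- normalize_spectrum(spec)
  if (width_ppm <= 0) abort("width_ppm must be > 0")
  x <- spec$ppm
  y <- spec$intensity
  lo0 <- floor(min(x) / width_ppm) * width_ppm
  edges_lo <- seq(lo0, max(x), by = width_ppm)
  mids <- (x[-length(x)] + x[-1]) / 2
  areas <- diff(x) * (y[-length(y)] + y[-1]) / 2
  idx <- floor((mids - lo0) / width_ppm) + 1L
  vals <- vapply(seq_along(edges_lo), function(b) sum(areas[idx == b]), numeric(1))
  out <- tibble(lo_ppm = edges_lo, hi_ppm = edges_lo + width_ppm, value = vals)
  if (length(exclusions)) {
    excl <- do.call(rbind, lapply(exclusions, function(e) sort(e[1:2])))
    overlaps <- vapply(seq_len(nrow(out)), function(i) {
      any(out$lo_ppm[i] < excl[, 2] & out$hi_ppm[i] > excl[, 1])
    }, logical(1))
    out <- out[!overlaps, ]
  }
  if (nrow(out) == 0) abort("exclusions cover the whole spectral range")
  out
}

#' Conventional exclusion regions for faecal 1H spectra
#'
#' Water (4.50-5.20 ppm), the TSP reference region (-0.50-0.50 ppm) and
#' the spectrum extremes outside 0.50-9.00 ppm. The published bucket count
#' of a given study depends on its (unstated) exclusion bounds, so these
#' are configuration, not constants to reproduce.
#' @return List of `c(lo, hi)` ppm intervals.
#' @export
default_nmr_exclusions <- function() {
  list(c(4.50, 5.20), c(-0.50, 0.50), c(-Inf, 0.50), c(9.00, Inf))
}

#' Build a bucket matrix from a list of spectra
#'
#' Applies [bucket_spectrum()] to each spectrum (which must share a grid so
#' bucket edges agree) and stacks the results into a samples-by-buckets
#' tibble with `sample_id` first and bucket columns named `ppm_<lo>`.
#'
#' @inheritParams bucket_spectrum
#' @param spectra Named list of spectrum tibbles.
#' @return Bucket-matrix tibble with attribute `normalization = "raw"` and
#'   attribute `bucket_edges`.
#' @export
bucket_spectra <- function(spectra, width_ppm = 0.02,
                           exclusions = default_nmr_exclusions()) {
  if (is.null(names(spectra))) names(spectra) <- sprintf("s%02d", seq_along(spectra))
  per <- lapply(spectra, bucket_spectrum, width_ppm = width_ppm,
                exclusions = exclusions)
  edges <- per[[1]][c("lo_ppm", "hi_ppm")]
  m <- t(vapply(per, function(b) b$value, numeric(nrow(edges))))
  colnames(m) <- sprintf("ppm_%.3f", edges$lo_ppm)
  rownames(m) <- names(spectra)
  out <- matrix_to_tbl(m)
  attr(out, "bucket_edges") <- edges
  attr(out, "normalization") <- "raw"
  out
}

#' Total-integral normalization of a bucket matrix
#'
#' Scales every row so that the sum over buckets equals `total`
#' (1000 by convention). Idempotent.
#'
#' @param m Bucket-matrix tibble.
#' @param total Target row sum.
#' @return Normalized tibble with attribute `normalization = "total<total>"`.
#' @export
total_integral_normalize <- function(m, total = 1000) {
  mat <- feature_matrix(m)
  sums <- rowSums(mat)
  if (any(sums <= 0)) {
    abort(sprintf("zero-total row(s): %s",
                  paste(rownames(mat)[sums <= 0], collapse = ", ")))
  }
  out <- matrix_to_tbl(mat / sums * total)
  attr(out, "bucket_edges") <- attr(m, "bucket_edges")
  attr(out, "normalization") <- sprintf("total%g", total)
  attr(out, "total") <- total
  out
}

#' Probabilistic quotient normalization (PQN)
#'
#' Divides each spectrum row by its most probable dilution quotient: the
#' median, over buckets with positive reference value, of the ratio of the
#' sample to the reference spectrum. The reference is the per-bucket
#' median over all samples (or over a stated group).
#'
#' By convention PQN follows total-integral normalization, and that order
#' is enforced by default. Running it directly on raw (diluted) intensities
#' with `enforce_total = FALSE` instead makes the returned quotients
#' estimates of the per-sample dilution factors themselves.
#'
#' @param m Bucket-matrix tibble (>= 3 samples).
#' @param reference `"median_all"` (default) or `"median_of_group"`.
#' @param groups Required for `"median_of_group"`: data frame
#'   (`sample_id`, `group`); the reference is the median over the most
#'   frequent group.
#' @param enforce_total If `TRUE` (default) require a prior
#'   [total_integral_normalize()] pass.
#' @return The normalized tibble; the per-sample quotients are attached as
#'   attribute `"quotients"` (named numeric).
#' @export
pqn_normalize <- function(m, reference = c("median_all", "median_of_group"),
                          groups = NULL, enforce_total = TRUE) {
  reference <- match.arg(reference)
  norm_tag <- attr(m, "normalization") %||% "raw"
  if (enforce_total && !grepl("^total", norm_tag)) {
    abort("pqn_normalize expects a total-integral-normalized matrix (or enforce_total = FALSE)")
  }
  mat <- feature_matrix(m)
  if (nrow(mat) < 3) abort("PQN needs at least 3 samples")
  ref_rows <- mat
  if (reference == "median_of_group") {
    if (is.null(groups)) abort("groups required for median_of_group reference")
    g <- setNames(as.character(groups$group), groups$sample_id)[rownames(mat)]
    top <- names(sort(table(g), decreasing = TRUE))[1]
    ref_rows <- mat[which(g == top), , drop = FALSE]
  }
  ref <- apply(ref_rows, 2, median)
  if (all(ref <= 0)) abort("reference spectrum is all zero")
  usable <- ref > 0
  quotients <- apply(mat, 1, function(row) median(row[usable] / ref[usable]))
  if (any(quotients <= 0)) {
    abort(sprintf("non-positive quotient for sample(s): %s",
                  paste(rownames(mat)[quotients <= 0], collapse = ", ")))
  }
  out <- matrix_to_tbl(mat / quotients)
  attr(out, "bucket_edges") <- attr(m, "bucket_edges")
  attr(out, "normalization") <- paste0(norm_tag, "+pqn")
  attr(out, "quotients") <- quotients
  out
}

#' Select informative buckets by coefficient of variation
#'
#' Keeps the buckets whose across-sample coefficient of variation
#' (sd / mean) is at least `min_cv`. Most buckets of a normalized
#' spectrum are chemically uninteresting filler with only instrument
#' noise; the metabolite features carried into the co-occurrence network
#' are the high-variance buckets. Run this after normalization so that
#' dilution does not inflate every bucket's CV.
#'
#' @param m Bucket-matrix tibble.
#' @param min_cv Minimum coefficient of variation (default 0.1).
#' @return The tibble restricted to informative buckets.
#' @export
select_informative_buckets <- function(m, min_cv = 0.1) {
  mat <- feature_matrix(m)
  mu <- colMeans(mat)
  cv <- apply(mat, 2, sd) / ifelse(mu == 0, 1, mu)
  keep <- cv >= min_cv
  if (!any(keep)) warn("no buckets pass the CV filter")
  out <- m[c(TRUE, keep)]
  attr(out, "normalization") <- attr(m, "normalization")
  out
}

#' Full spectral preprocessing pipeline
#'
#' Runs the enforced stage order baseline removal -> alignment ->
#' bucketing -> total-integral normalization -> PQN and returns the final
#' bucket matrix. Stage provenance is recorded in the `normalization`
#' attribute and the applied shifts / quotients are carried along.
#'
#' @param spectra Named list of raw spectrum tibbles on a common grid.
#' @param radius_points Rolling-ball window half-width.
#' @param max_shift_ppm Alignment bound.
#' @param width_ppm Bucket width.
#' @param exclusions Exclusion intervals.
#' @param total Total-integral target.
#' @return PQN-normalized bucket matrix tibble (attributes: `shifts`,
#'   `quotients`, `bucket_edges`, `normalization`).
#' @export
preprocess_spectra <- function(spectra, radius_points = 50,
                               max_shift_ppm = 0.02, width_ppm = 0.02,
                               exclusions = default_nmr_exclusions(),
                               total = 1000) {
  corrected <- lapply(spectra, rolling_ball_baseline, radius_points = radius_points)
  names(corrected) <- names(spectra)
  aligned <- align_spectra(corrected, max_shift_ppm = max_shift_ppm)
  names(aligned) <- names(spectra)
  shifts <- attr(aligned, "shifts")
  m <- bucket_spectra(aligned, width_ppm = width_ppm, exclusions = exclusions)
  m <- total_integral_normalize(m, total = total)
  m <- pqn_normalize(m)
  attr(m, "shifts") <- shifts
  m
}
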