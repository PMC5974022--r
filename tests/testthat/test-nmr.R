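make_spec <- function(ppm, intensity) tibble::tibble(ppm = ppm, intensity = intensity)

test_that("rolling-ball baseline removal is exact on flat and benign on peaks", {
  grid <- seq(0, 10, by = 0.005)
  flat <- make_spec(grid, rep(3, length(grid)))
  out <- rolling_ball_baseline(flat, 50)
  expect_lt(max(abs(out$intensity)), 1e-12)

  # narrow peak, wide window: area preserved within 1%
  peak <- generate_raw_spectrum(data.frame(center = 5, width = 0.01, area = 4),
                                grid)
  corr <- rolling_ball_baseline(peak, 100)
  area_in <- sum(peak$intensity) * 0.005
  area_out <- sum(corr$intensity) * 0.005
  expect_lt(abs(area_out - area_in) / area_in, 0.01)

  # linear ramp + peak: residual baseline RMS < 5% of ramp amplitude
  ramp <- peak
  ramp$intensity <- ramp$intensity + seq(0, 2, length.out = nrow(ramp))
  corr2 <- rolling_ball_baseline(ramp, 100)
  off_peak <- abs(corr2$ppm - 5) > 0.1
  expect_lt(sqrt(mean(corr2$intensity[off_peak]^2)), 0.05 * 2)

  expect_error(rolling_ball_baseline(flat, length(grid)), "smaller")
  expect_error(rolling_ball_baseline(flat, 0), ">= 1")
})

test_that("bucketing integrates additively and honours exclusions", {
  grid <- seq(0.5, 9, by = 0.001)
  # peak fully inside bucket [2.48, 2.50): 3 sigma containment
  sp <- generate_raw_spectrum(data.frame(center = 2.49, width = 0.003, area = 6),
                              grid)
  b <- bucket_spectrum(sp, exclusions = list())
  top <- b[which.max(b$value), ]
  expect_equal(top$lo_ppm, 2.48)
  expect_gte(top$value / sum(b$value), 0.997)

  # no exclusions: bucket total equals the full trapezoidal integral
  total <- sum(diff(sp$ppm) * (head(sp$intensity, -1) + sp$intensity[-1]) / 2)
  expect_equal(sum(b$value), total, tolerance = 1e-9)

  # an exclusion interval drops exactly the overlapping buckets
  excl <- list(c(4.5, 5.2))
  b2 <- bucket_spectrum(sp, exclusions = excl)
  dropped <- setdiff(b$lo_ppm, b2$lo_ppm)
  oracle <- b$lo_ppm[b$lo_ppm < 5.2 & b$lo_ppm + 0.02 > 4.5]
  expect_setequal(dropped, oracle)

  expect_error(bucket_spectrum(sp, exclusions = list(c(-Inf, Inf))), "whole")
  expect_error(bucket_spectrum(sp, width_ppm = 0), "width")
})

test_that("total-integral normalization hits the target exactly and is idempotent", {
  m <- tibble::tibble(sample_id = c("a", "b"), x = c(1, 10), y = c(1, 10), z = c(2, 20))
  n1 <- total_integral_normalize(m)
  expect_equal(unlist(n1[1, -1]), c(x = 250, y = 250, z = 500))
  expect_equal(rowSums(as.matrix(n1[-1])), c(1000, 1000), ignore_attr = TRUE)
  n2 <- total_integral_normalize(n1)
  expect_equal(as.data.frame(n2), as.data.frame(n1), tolerance = 1e-12)
  expect_error(
    total_integral_normalize(tibble::tibble(sample_id = "a", x = 0, y = 0)),
    "zero"
  )
  # synthetic cohort rows sum to 1000 within 1e-9
  coh <- generate_cohort(cohort_spec(seed = 2, n_cases = 5, n_controls = 5))
  nm <- total_integral_normalize(coh$nmr)
  expect_lt(max(abs(rowSums(as.matrix(nm[-1])) - 1000)), 1e-9)
})

test_that("PQN returns unit quotients for identical rows and scales known dilutions", {
  base <- c(x = 10, y = 20, z = 30, w = 40)
  m <- tibble::tibble(sample_id = c("a", "b", "c"),
                      x = rep(10, 3), y = rep(20, 3), z = rep(30, 3), w = rep(40, 3))
  pq <- pqn_normalize(m, enforce_total = FALSE)
  expect_equal(unname(attr(pq, "quotients")), rep(1, 3))
  expect_equal(as.matrix(pq[-1]), as.matrix(m[-1]), ignore_attr = TRUE)

  # a doubled row (total normalization bypassed) gets quotient 2 and is halved
  m2 <- m
  m2[2, -1] <- as.list(2 * base)
  pq2 <- pqn_normalize(m2, enforce_total = FALSE)
  expect_equal(unname(attr(pq2, "quotients")[2]), 2)
  expect_equal(unlist(pq2[2, -1]), base)

  expect_error(pqn_normalize(m2), "total")
  expect_error(pqn_normalize(m[1:2, ], enforce_total = FALSE), "3 samples")
})

test_that("PQN recovers planted dilution factors from the synthetic cohort", {
  coh <- generate_cohort(cohort_spec(seed = 17))
  pq <- pqn_normalize(coh$nmr, enforce_total = FALSE)
  q <- attr(pq, "quotients")
  truth <- coh$truth$dilution_factors
  expect_gte(cor(q[truth$sample_id], truth$dilution), 0.99)
})

test_that("PQN after total normalization preserves the rank order of a dominant bucket", {
  withr::with_seed(6, {
    n <- 8
    small <- matrix(runif(n * 9, 5, 10), n, 9)
    colnames(small) <- letters[1:9]
    m <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("s", 1:n), big = runif(n, 50, 150)),
      tibble::as_tibble(small)
    )
  })
  # the median quotient comes from the stable small buckets, so dividing
  # by it undoes the total-normalization distortion of the dominant bucket
  norm <- pqn_normalize(total_integral_normalize(m))
  expect_identical(order(norm$big), order(m$big))
  expect_match(attr(norm, "normalization"), "total1000\\+pqn")
})

test_that("alignment recovers constructed rigid shifts and ignores scaling", {
  grid <- seq(1, 3, by = 0.001)
  ref <- generate_raw_spectrum(data.frame(center = 2, width = 0.01, area = 5), grid)
  shift_pts <- 10 # +0.01 ppm
  shifted <- ref
  shifted$intensity <- c(rep(0, shift_pts), ref$intensity[1:(nrow(ref) - shift_pts)])
  out <- align_spectra(list(ref, ref, shifted), max_shift_ppm = 0.02)
  expect_equal(attr(out, "shifts"), c(0, 0, -0.01))

  scaled <- shifted
  scaled$intensity <- 37 * scaled$intensity
  out2 <- align_spectra(list(ref, ref, scaled), max_shift_ppm = 0.02)
  expect_equal(attr(out2, "shifts"), c(0, 0, -0.01))

  expect_equal(attr(align_spectra(list(ref, ref, ref)), "shifts"), c(0, 0, 0))
  expect_error(align_spectra(list(ref, ref), max_shift_ppm = 10), "span")
})

test_that("the spectral pipeline runs stages in order and records provenance", {
  grid <- seq(0.5, 9, by = 0.002)
  peaks <- data.frame(center = c(1.3, 2.5, 3.7), width = 0.01, area = c(4, 6, 2))
  specs <- lapply(1:4, function(i) {
    sp <- generate_raw_spectrum(peaks, grid, baseline_amplitude = 0.3,
                                noise_sd = 0.005, seed = i)
    sp$intensity <- sp$intensity * c(0.8, 1, 1.2, 1.5)[i]
    sp
  })
  names(specs) <- paste0("s", 1:4)
  m <- preprocess_spectra(specs)
  expect_identical(attr(m, "normalization"), "total1000+pqn")
  expect_equal(nrow(m), 4)
  expect_length(attr(m, "quotients"), 4)
  expect_length(attr(m, "shifts"), 4)
})
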