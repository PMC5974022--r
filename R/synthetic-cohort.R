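#' Specification for a synthetic microbiome-metabolome cohort
#'
#' Defines the generating conditions for [generate_cohort()]: a two-arm
#' faecal cohort (cirrhotic cases vs healthy controls) with planted
#' correlation-block structure shared between taxa and metabolites, bridge
#' ("keystone") features connecting pairs of blocks, per-sample NMR dilution
#' factors, and a binary hepatic-encephalopathy (HE) outcome drawn from a
#' logistic model on chosen feature latents.
#'
#' The defaults emulate the faecal arm of the motivating cirrhosis study:
#' 35 cases and 14 controls, read depths bounded below by 3101 (the
#' rarefaction depth), an HE intercept giving a marginal prevalence of
#' 8/46, and HE coefficients with the magnitudes of the published
#' logistic betas. Planted taxa share roughly 45% of the community; the
#' remaining mass is spread over `n_background` low-abundance background
#' taxa that fall below the 0.5% mean-abundance filter, mimicking the long
#' tail of rare OTUs and damping compositional closure effects.
#'
#' @param n_cases,n_controls Number of case / control samples.
#' @param n_taxa Number of planted (block-structured) taxa.
#' @param n_metabolites Number of planted metabolite buckets.
#' @param n_blocks Number of planted functional blocks (FMCs).
#' @param block_corr Within-block latent correlation, strictly in (0, 1).
#' @param n_keystones Number of bridge features, each loading 1/sqrt(2) on
#'   two adjacent blocks.
#' @param keystone_kind Which feature kind carries the bridges:
#'   `"metabolite"` (default; intensities carry no counting noise),
#'   `"taxon"`, or `"alternate"`.
#' @param bridge_corr Correlation of the shared factor given to each
#'   bridged block pair, in `[0, 1)`. With fully orthogonal blocks a
#'   1/sqrt(2) bridge cannot exceed population correlation
#'   `sqrt(block_corr / 2)` to either block, which sits below the 0.7
#'   edge threshold; a weak shared factor makes bridges detectable while
#'   leaving across-block member correlations (`block_corr * bridge_corr`)
#'   far below it.
#' @param frac_negative Fraction of planted non-keystone features loading
#'   negatively on their block factor; these give the network its
#'   competitive (negative-correlation) edges.
#' @param n_background Number of sub-threshold background taxa.
#' @param n_background_buckets Number of low-variance background NMR
#'   buckets carrying the bulk of the total integral.
#' @param depth_range Integer pair: range of per-sample library sizes.
#' @param dilution_range Positive pair: range of per-sample NMR dilution
#'   factors (log-uniform draw).
#' @param he_beta Named numeric vector of logistic coefficients on feature
#'   latents generating the HE label. Names must be feature ids.
#' @param he_intercept Logistic intercept; default `qlogis(8/46)`.
#' @param clinical_assoc Named list describing clinical parameters that are
#'   correlated with a feature latent: each element is
#'   `list(feature = <id>, r = <target correlation>)`. Unlisted clinical
#'   columns are independent noise.
#' @param noise_sd Standard deviation of measurement noise added to
#'   metabolite intensities.
#' @param seed Master seed; one RNG stream per output block is derived from
#'   it so adding outputs never perturbs existing ones.
#' @return A list of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_cases = 35, n_controls = 14,
                        n_taxa = 20, n_metabolites = 20,
                        n_blocks = 4, block_corr = 0.9,
                        n_keystones = 2,
                        keystone_kind = c("metabolite", "taxon", "alternate"),
                        bridge_corr = 0.45, frac_negative = 0.1,
                        n_background = 300, n_background_buckets = 150,
                        depth_range = c(3101L, 50000L),
                        dilution_range = c(0.5, 2),
                        he_beta = c(met01 = 1.275, met02 = 0.772, met03 = -0.371),
                        he_intercept = stats::qlogis(8 / 46),
                        clinical_assoc = list(
                          MELD = list(feature = "met01", r = 0.8),
                          CRP = list(feature = "Otu001", r = 0.8)
                        ),
                        noise_sd = 0.05, seed = 1L) {
  keystone_kind <- match.arg(keystone_kind)
  spec <- list(
    n_cases = n_cases, n_controls = n_controls, n_taxa = n_taxa,
    n_metabolites = n_metabolites, n_blocks = n_blocks,
    block_corr = block_corr, n_keystones = n_keystones,
    keystone_kind = keystone_kind, bridge_corr = bridge_corr,
    frac_negative = frac_negative,
    n_background = n_background,
    n_background_buckets = n_background_buckets, depth_range = depth_range,
    dilution_range = dilution_range, he_beta = he_beta,
    he_intercept = he_intercept, clinical_assoc = clinical_assoc,
    noise_sd = noise_sd, seed = seed
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid cohort spec field '%s': %s", field, msg))
  }
  counts <- c("n_cases", "n_controls", "n_taxa", "n_metabolites", "n_blocks",
              "n_background", "n_background_buckets")
  for (f in counts) {
    chk(length(spec[[f]]) == 1 && is.finite(spec[[f]]) && spec[[f]] >= 0 &&
          spec[[f]] == round(spec[[f]]), f, "must be a non-negative integer")
  }
  chk(spec$n_cases >= 1 && spec$n_controls >= 1, "n_cases", "need both arms")
  chk(spec$n_taxa >= 1 && spec$n_metabolites >= 1, "n_taxa", "must be positive")
  chk(spec$n_blocks >= 1, "n_blocks", "must be >= 1")
  chk(spec$block_corr > 0 && spec$block_corr < 1, "block_corr",
      "must lie strictly in (0, 1)")
  chk(spec$bridge_corr >= 0 && spec$bridge_corr < 1, "bridge_corr",
      "must lie in [0, 1)")
  chk(spec$frac_negative >= 0 && spec$frac_negative < 1, "frac_negative",
      "must lie in [0, 1)")
  chk(spec$n_keystones >= 0 && spec$n_keystones == round(spec$n_keystones),
      "n_keystones", "must be a non-negative integer")
  chk(length(spec$depth_range) == 2 && all(spec$depth_range >= 1) &&
        spec$depth_range[1] <= spec$depth_range[2],
      "depth_range", "must be an increasing positive pair")
  chk(length(spec$dilution_range) == 2 && spec$dilution_range[1] > 0 &&
        spec$dilution_range[1] <= spec$dilution_range[2],
      "dilution_range", "lower bound must be > 0")
  chk(spec$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(length(spec$seed) == 1 && is.finite(spec$seed), "seed",
      "must be a single finite number")
  invisible(spec)
}

# sd of z_a + z_b given the shared-factor construction
sd_sum_blocks <- function(gam, a, b, bridged_pairs, n_blocks) {
  if (a == b) return(2)
  k <- tabulate(unlist(bridged_pairs), nbins = n_blocks)
  n_shared <- sum(vapply(bridged_pairs, function(p) all(c(a, b) %in% p),
                         logical(1)))
  corr_ab <- if (gam > 0) {
    gam * n_shared / sqrt((1 + gam * k[a]) * (1 + gam * k[b]))
  } else 0
  sqrt(2 + 2 * corr_ab)
}

# Feature ids for a spec.
cohort_feature_ids <- function(spec) {
  list(
    taxa = sprintf("Otu%03d", seq_len(spec$n_taxa)),
    metabolites = sprintf("met%02d", seq_len(spec$n_metabolites)),
    background = sprintf("Bg%03d", seq_len(spec$n_background)),
    bg_buckets = sprintf("bgbkt%03d", seq_len(spec$n_background_buckets))
  )
}

#' Generate a synthetic coupled microbiome / metabolome / clinical cohort
#'
#' Draws a cohort under a [cohort_spec()]: per-block standard-normal latent
#' factors per sample; each planted feature's latent is
#' `sqrt(block_corr) * factor + sqrt(1 - block_corr) * noise`; keystone
#' bridge features load `1/sqrt(2)` on each of two blocks. Taxon latents
#' pass through a softmax to relative abundances and a per-sample
#' multinomial draw at a library size from `depth_range`; metabolites are
#' noisy linear images of their latents, scaled by per-sample dilution
#' factors. HE labels are Bernoulli with
#' `logit p = he_intercept + sum(he_beta * latent)`.
#'
#' Fully reproducible for a fixed seed: counts, NMR, clinical values and
#' labels are drawn from independent RNG streams derived from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `fmn_cohort` with elements
#'   * `counts`: tibble, `sample_id` + taxon count columns (planted then
#'     background taxa); rows sum to the drawn library size;
#'   * `nmr`: tibble, `sample_id` + metabolite intensity columns (already
#'     multiplied by the dilution factor);
#'   * `clinical`: tibble with `sample_id`, `group` (case/control), `he`
#'     (0/1) and numeric clinical columns;
#'   * `truth`: the planted structure (class `fmn_planted`): feature-block
#'     map, keystone ids, dilution factors, HE labels and generating betas.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_cases = 10, n_controls = 5, seed = 42))
#' dim(coh$counts)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  seeds <- derive_seeds(spec$seed, c("latents", "counts", "nmr", "clinical", "labels"))
  ids <- cohort_feature_ids(spec)
  n <- spec$n_cases + spec$n_controls
  sample_ids <- c(sprintf("case_%02d", seq_len(spec$n_cases)),
                  sprintf("ctrl_%02d", seq_len(spec$n_controls)))
  rho <- spec$block_corr

  planted <- c(ids$taxa, ids$metabolites)
  kind <- c(rep("taxon", spec$n_taxa), rep("metabolite", spec$n_metabolites))
  # round-robin block assignment, taxa and metabolites interleaved over blocks
  block <- rep_len(seq_len(spec$n_blocks), length(planted))

  # keystones bridge adjacent block pairs; drawn from the end of the
  # feature list of the configured kind (metabolites by default: bucket
  # intensities carry no multinomial counting noise, so bridge
  # correlations survive thresholding)
  n_ks <- min(spec$n_keystones, length(planted))
  ks_idx <- integer(0)
  if (n_ks > 0) {
    tax_pool <- rev(which(kind == "taxon"))
    met_pool <- rev(which(kind == "metabolite"))
    for (i in seq_len(n_ks)) {
      pool <- switch(spec$keystone_kind,
        metabolite = met_pool,
        taxon = tax_pool,
        alternate = if (i %% 2 == 1) met_pool else tax_pool
      )
      pick <- setdiff(pool, ks_idx)[1]
      if (is.na(pick)) pick <- setdiff(rev(seq_along(planted)), ks_idx)[1]
      ks_idx <- c(ks_idx, pick)
    }
  }
  ks_second_block <- (block[ks_idx] %% spec$n_blocks) + 1L
  if (spec$n_blocks == 1) ks_second_block <- block[ks_idx]

  # bridged block pairs share a weak common factor (bridge_corr): with
  # orthogonal blocks a 1/sqrt(2) bridge is capped at population
  # correlation sqrt(block_corr / 2) < 0.7 to either block, so its edges
  # would never survive thresholding; a shared factor lifts the bridge to
  # block_corr * sqrt((1 + c) / 2) while across-block member correlation
  # stays at block_corr * c, far below the edge threshold
  bridged_pairs <- unique(lapply(seq_along(ks_idx), function(j) {
    sort(c(block[ks_idx[j]], ks_second_block[j]))
  }))
  bridged_pairs <- bridged_pairs[vapply(bridged_pairs, function(p) {
    p[1] != p[2]
  }, logical(1))]
  cb <- spec$bridge_corr
  gam <- if (cb > 0) cb / (1 - cb) else 0

  latents <- with_seed(seeds[["latents"]], {
    u <- matrix(rnorm(n * spec$n_blocks), n, spec$n_blocks)
    z <- u
    if (gam > 0 && length(bridged_pairs)) {
      shared <- matrix(rnorm(n * length(bridged_pairs)), n)
      k_b <- tabulate(unlist(bridged_pairs), nbins = spec$n_blocks)
      for (b in seq_len(spec$n_blocks)) {
        in_pair <- which(vapply(bridged_pairs, function(p) b %in% p, logical(1)))
        if (length(in_pair)) {
          z[, b] <- (u[, b] + sqrt(gam) * rowSums(shared[, in_pair, drop = FALSE])) /
            sqrt(1 + gam * k_b[b])
        }
      }
    }
    eps <- matrix(rnorm(n * length(planted)), n, length(planted))
    x <- sqrt(rho) * z[, block, drop = FALSE] + sqrt(1 - rho) * eps
    # keystones are pure bridges (no idiosyncratic term): equal 1/sqrt(2)
    # weight on each bridged block factor, rescaled to unit variance
    for (j in seq_along(ks_idx)) {
      i <- ks_idx[j]
      zsum <- z[, block[i]] + z[, ks_second_block[j]]
      x[, i] <- zsum / sd_sum_blocks(gam, block[i], ks_second_block[j],
                                     bridged_pairs, spec$n_blocks)
    }
    colnames(x) <- planted
    list(z = z, x = x)
  })
  x <- latents$x

  # a deterministic, evenly spaced subset of non-keystone features loads
  # negatively on its block: these become the competitive edges
  nonks <- setdiff(seq_along(planted), ks_idx)
  n_neg <- floor(spec$frac_negative * length(nonks))
  neg_idx <- if (n_neg > 0) {
    nonks[round(seq(2, length(nonks), length.out = n_neg))]
  } else integer(0)
  if (length(neg_idx)) x[, neg_idx] <- -x[, neg_idx]

  # --- counts: softmax over planted + background log-weights ---------------
  # planted taxa share ~18% of the community with lognormal spread
  # (~0.9% each, clearing the 0.5% mean-abundance filter); the long tail
  # of sub-threshold background taxa carries the remaining mass, which
  # both mimics rare-OTU structure and damps compositional closure
  counts <- with_seed(seeds[["counts"]], {
    n_tax <- spec$n_taxa
    planted_share <- 0.18
    mu_tax <- log(planted_share / n_tax) + rnorm(n_tax, 0, 0.25)
    logw <- sweep(0.6 * x[, seq_len(n_tax), drop = FALSE], 2, mu_tax, "+")
    if (spec$n_background > 0) {
      mu_bg <- log((1 - planted_share) / spec$n_background) +
        rnorm(spec$n_background, 0, 0.15)
      bg <- matrix(rnorm(n * spec$n_background, 0, 0.3), n, spec$n_background)
      logw <- cbind(logw, sweep(bg, 2, mu_bg, "+"))
    }
    w <- exp(logw)
    p <- w / rowSums(w)
    depth <- as.integer(round(runif(n, spec$depth_range[1], spec$depth_range[2])))
    cnt <- t(vapply(seq_len(n), function(i) {
      as.numeric(rmultinom(1, depth[i], p[i, ]))
    }, numeric(ncol(p))))
    colnames(cnt) <- c(ids$taxa, ids$background)
    rownames(cnt) <- sample_ids
    cnt
  })

  # --- NMR: linear images of metabolite latents, diluted -------------------
  # planted buckets are high-CV peaks (intensity ~10 + 2*latent, CV ~20%);
  # background buckets are low-CV filler carrying most of the total
  # integral, as in a real bucket table where informative peaks are a
  # small share of the spectrum
  nmr_out <- with_seed(seeds[["nmr"]], {
    n_met <- spec$n_metabolites
    xm <- x[, spec$n_taxa + seq_len(n_met), drop = FALSE]
    a_f <- 10 * exp(rnorm(n_met, 0, 0.2))
    base <- sweep(0.2 * xm + spec$noise_sd / 10 *
                    matrix(rnorm(n * n_met), n, n_met) + 1, 2, a_f, "*")
    if (spec$n_background_buckets > 0) {
      a_bg <- (10 * n_met * (1 - 0.18) / 0.18 / spec$n_background_buckets) *
        exp(rnorm(spec$n_background_buckets, 0, 0.2))
      bgb <- sweep(1 + 0.05 * matrix(rnorm(n * spec$n_background_buckets),
                                     n, spec$n_background_buckets),
                   2, a_bg, "*")
      base <- cbind(base, bgb)
    }
    base[base < 0] <- 0
    dil <- exp(runif(n, log(spec$dilution_range[1]), log(spec$dilution_range[2])))
    m <- base * dil
    colnames(m) <- c(ids$metabolites, ids$bg_buckets)
    rownames(m) <- sample_ids
    list(m = m, dil = setNames(dil, sample_ids))
  })

  # --- HE labels ------------------------------------------------------------
  betas <- spec$he_beta %||% numeric(0)
  unknown <- setdiff(names(betas), planted)
  if (length(unknown)) {
    abort(sprintf("invalid cohort spec field 'he_beta': unknown feature(s) %s",
                  paste(unknown, collapse = ", ")))
  }
  he <- with_seed(seeds[["labels"]], {
    eta <- rep(spec$he_intercept, n)
    for (f in names(betas)) eta <- eta + betas[[f]] * x[, f]
    as.integer(rbinom(n, 1, stats::plogis(eta)))
  })

  # --- clinical table -------------------------------------------------------
  clinical <- with_seed(seeds[["clinical"]], {
    params <- list(
      age = round(rnorm(n, 58, 10), 1),
      WBC = round(exp(rnorm(n, log(6), 0.3)), 2),
      IL6 = round(exp(rnorm(n, log(8), 0.5)), 2)
    )
    for (pn in names(spec$clinical_assoc)) {
      a <- spec$clinical_assoc[[pn]]
      if (!a$feature %in% planted) {
        abort(sprintf("invalid cohort spec field 'clinical_assoc': unknown feature '%s'",
                      a$feature))
      }
      zf <- x[, a$feature]
      params[[pn]] <- round(a$r * zf + sqrt(1 - a$r^2) * rnorm(n), 3)
    }
    bind_cols(
      tibble(sample_id = sample_ids,
             group = c(rep("case", spec$n_cases), rep("control", spec$n_controls)),
             he = he),
      as_tibble(params)
    )
  })

  truth <- structure(list(
    block_of_feature = tibble(
      feature = c(planted, ids$background, ids$bg_buckets),
      kind = c(kind, rep("taxon", spec$n_background),
               rep("metabolite", spec$n_background_buckets)),
      block = c(block, rep(0L, spec$n_background + spec$n_background_buckets))
    ),
    keystone_ids = planted[ks_idx],
    negative_features = planted[neg_idx],
    keystone_blocks = if (length(ks_idx)) {
      tibble(feature = planted[ks_idx], block_a = block[ks_idx],
             block_b = ks_second_block)
    } else tibble(feature = character(), block_a = integer(), block_b = integer()),
    dilution_factors = tibble(sample_id = sample_ids,
                              dilution = unname(nmr_out$dil)),
    he_labels = tibble(sample_id = sample_ids, he = he),
    generating_betas = betas,
    he_intercept = spec$he_intercept,
    latents = structure(x, dimnames = list(sample_ids, planted))
  ), class = "fmn_planted")

  structure(list(
    counts = matrix_to_tbl(counts),
    nmr = matrix_to_tbl(nmr_out$m),
    clinical = clinical,
    truth = truth,
    spec = spec
  ), class = "fmn_cohort")
}

#' @export
print.fmn_cohort <- function(x, ...) {
  cat(sprintf("<fmn_cohort> %d samples (%d cases, %d controls), %d taxa (+%d background), %d metabolites, seed %s\n",
              nrow(x$counts), x$spec$n_cases, x$spec$n_controls,
              x$spec$n_taxa, x$spec$n_background, x$spec$n_metabolites,
              format(x$spec$seed)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the three tables as TSV files with a `#seed=` header comment and
#' the planted structure as JSON.
#'
#' @param cohort An `fmn_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fmn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("#seed=%s", format(cohort$spec$seed))
  wr <- function(tbl, name) {
    path <- file.path(dir, name)
    writeLines(hdr, path)
    suppressMessages(readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE))
  }
  wr(cohort$counts, "counts.tsv")
  wr(cohort$nmr, "nmr.tsv")
  wr(cohort$clinical, "clinical.tsv")
  truth <- unclass(cohort$truth)
  truth$latents <- NULL
  jsonlite::write_json(truth, file.path(dir, "planted_structure.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Simulate a 1D NMR spectrum from a peak list
#'
#' Builds a synthetic proton spectrum as a sum of Gaussian peaks plus a
#' smooth low-frequency baseline plus white noise. Peak areas are
#' recoverable by numerical integration, which makes the output a
#' convenient fixture for baseline-removal and bucketing routines.
#'
#' @param peaks Data frame with columns `center` (ppm), `width` (Gaussian
#'   sigma, ppm, > 0) and `area` (integrated intensity).
#' @param ppm_grid Strictly monotone numeric vector of chemical shifts.
#' @param baseline_amplitude Amplitude of the smooth baseline (0 = none).
#' @param noise_sd Standard deviation of additive white noise.
#' @param seed Seed for the baseline phases and the noise.
#' @return A tibble with columns `ppm` (ascending) and `intensity`.
#' @examples
#' sp <- generate_raw_spectrum(
#'   data.frame(center = 2, width = 0.01, area = 5),
#'   ppm_grid = seq(0.5, 9, by = 0.001)
#' )
#' @export
generate_raw_spectrum <- function(peaks, ppm_grid, baseline_amplitude = 0,
                                  noise_sd = 0, seed = 1L) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "width", "area") %in% names(peaks)))
  d <- diff(ppm_grid)
  if (length(ppm_grid) < 2 || !(all(d > 0) || all(d < 0))) {
    abort("ppm_grid must be strictly monotone")
  }
  ppm <- sort(ppm_grid)
  if (any(peaks$width <= 0)) abort("peak widths must be > 0")
  out_of_range <- peaks$center < min(ppm) | peaks$center > max(ppm)
  if (any(out_of_range)) {
    abort(sprintf("peak(s) at ppm %s lie outside the grid",
                  paste(format(peaks$center[out_of_range]), collapse = ", ")))
  }
  intensity <- rep(0, length(ppm))
  for (i in seq_len(nrow(peaks))) {
    intensity <- intensity + peaks$area[i] *
      stats::dnorm(ppm, peaks$center[i], peaks$width[i])
  }
  with_seed(seed, {
    if (baseline_amplitude != 0) {
      span <- diff(range(ppm))
      t <- (ppm - min(ppm)) / span
      phases <- runif(3, 0, 2 * pi)
      b <- cos(2 * pi * 1 * t + phases[1]) + 0.6 * cos(2 * pi * 2 * t + phases[2]) +
        0.3 * cos(2 * pi * 3 * t + phases[3])
      intensity <- intensity + baseline_amplitude * (b - min(b)) / diff(range(b))
    }
    if (noise_sd > 0) intensity <- intensity + rnorm(length(ppm), 0, noise_sd)
  })
  tibble(ppm = ppm, intensity = intensity)
}
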