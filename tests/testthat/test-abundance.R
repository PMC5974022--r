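test_that("abundance tables round-trip through TSV in either orientation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tt1\tt2", "s1\t3\t5", "s2\t2\t0"), path)
  tbl <- read_abundance_table(path)
  expect_identical(names(tbl), c("sample_id", "t1", "t2"))
  expect_identical(attr(tbl, "kind"), "counts")
  expect_equal(tbl$t1, c(3, 2))

  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2", "t1\t3\t2", "t2\t5\t0"), tpath)
  ttbl <- read_abundance_table(tpath, orientation = "taxa_in_rows")
  expect_equal(as.data.frame(ttbl), as.data.frame(tbl))

  # written tables read back identically
  out <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tbl, out)
  expect_equal(as.data.frame(read_abundance_table(out)), as.data.frame(tbl))
})

test_that("malformed abundance files fail with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tt1\tt2", "s1\t3\t-2", "s2\t2\t0"), path)
  expect_error(read_abundance_table(path), "s1.*t2")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tt1\tt1", "s1\t3\t2"), dup)
  expect_error(read_abundance_table(dup), "duplicate")
})

test_that("rarefaction conserves depth and leaves full-depth samples intact", {
  tbl <- tibble::tibble(sample_id = c("a", "b"), t1 = c(6, 50),
                        t2 = c(4, 30), t3 = c(0, 20))
  r <- suppressWarnings(rarefy_counts(tbl, depth = 10, seed = 2))
  expect_equal(rowSums(as.matrix(r[-1])), c(10, 10), ignore_attr = TRUE)
  # sample "a" already at depth 10: unchanged
  expect_equal(unlist(r[1, -1]), unlist(tbl[1, -1]))
  # reproducible per seed
  r2 <- suppressWarnings(rarefy_counts(tbl, depth = 10, seed = 2))
  expect_identical(r, r2)
  expect_error(rarefy_counts(tbl, depth = 11), "a")
})

test_that("rarefaction preserves expected composition (hypergeometric mean)", {
  tbl <- tibble::tibble(sample_id = "s", t1 = 120, t2 = 60, t3 = 20)
  props <- vapply(1:400, function(s) {
    r <- suppressWarnings(rarefy_counts(tbl, depth = 50, seed = s))
    r$t1 / 50
  }, numeric(1))
  # E[proportion] = original proportion 0.6; hypergeometric sd of the mean
  se <- sqrt(0.6 * 0.4 / 50 * (200 - 50) / (200 - 1) / 400)
  expect_lt(abs(mean(props) - 0.6), 4 * se)
})

test_that("relative abundance conversion normalizes rows and is idempotent", {
  tbl <- tibble::tibble(sample_id = "s", a = 2, b = 2)
  rel <- to_relative(tbl)
  expect_equal(unlist(rel[-1]), c(a = 0.5, b = 0.5))
  expect_equal(as.data.frame(to_relative(rel)), as.data.frame(rel))
  coh <- generate_cohort(cohort_spec(seed = 3, n_cases = 5, n_controls = 5))
  rel2 <- to_relative(suppressWarnings(rarefy_counts(coh$counts, 3101, seed = 1)))
  expect_equal(rowSums(as.matrix(rel2[-1])), rep(1, 10), ignore_attr = TRUE)
  expect_error(to_relative(tibble::tibble(sample_id = "s", a = 0, b = 0)), "s")
})

test_that("the mean-abundance filter keeps ties at the threshold (inclusive)", {
  tbl <- tibble::tibble(
    sample_id = c("s1", "s2"),
    keep_hi = c(0.008, 0.004),  # mean 0.006
    drop_lo = c(0.006, 0.002),  # mean 0.004
    keep_eq = c(0.005, 0.005),  # mean exactly 0.005
    rest = c(0.981, 0.989)
  )
  f <- filter_by_mean_abundance(tbl, 0.005)
  expect_identical(names(f), c("sample_id", "keep_hi", "keep_eq", "rest"))
  expect_identical(names(filter_by_mean_abundance(tbl, 0)), names(tbl))
  expect_warning(filter_by_mean_abundance(tbl, 0.999), "no taxa")
  # output means all clear the threshold
  expect_true(all(colMeans(as.matrix(f[-1])) >= 0.005))
})

test_that("alpha diversity matches closed forms and a direct-summation oracle", {
  uni <- tibble::tibble(sample_id = "u", a = 1, b = 1, c = 1, d = 1)
  expect_equal(alpha_diversity(uni)$shannon, log(4))
  expect_equal(alpha_diversity(uni)$observed_taxa, 4L)
  single <- tibble::tibble(sample_id = "s", a = 7, b = 0)
  expect_equal(alpha_diversity(single)$shannon, 0)
  expect_equal(alpha_diversity(single)$observed_taxa, 1L)

  tbl <- random_rel(4, 12, seed = 8)
  got <- alpha_diversity(tbl)
  m <- as.matrix(tbl[-1])
  for (i in 1:4) {
    p <- m[i, ] / sum(m[i, ])
    h <- 0
    for (v in p) if (v > 0) h <- h - v * log(v)
    expect_equal(got$shannon[i], h, tolerance = 1e-12)
  }
  expect_equal(alpha_diversity(tbl, base = 2)$shannon,
               got$shannon / log(2), tolerance = 1e-12)
})

test_that("beta dissimilarities match hand-evaluated formulas", {
  ident <- tibble::tibble(sample_id = c("a", "b"), x = c(0.3, 0.3), y = c(0.7, 0.7))
  for (m in c("yue_clayton", "bray_curtis")) {
    expect_equal(beta_dissimilarity(ident, m)$distance, 0)
  }
  disj <- tibble::tibble(sample_id = c("a", "b"), x = c(1, 0), y = c(0, 1))
  for (m in c("yue_clayton", "bray_curtis")) {
    expect_equal(beta_dissimilarity(disj, m)$distance, 1)
  }
  # theta for (0.5, 0.5) vs (0.25, 0.75) is exactly 0.2
  two <- tibble::tibble(sample_id = c("a", "b"), x = c(0.5, 0.25), y = c(0.5, 0.75))
  expect_equal(beta_dissimilarity(two, "yue_clayton")$distance, 0.2)
  expect_error(beta_dissimilarity(two, "unknown_metric"))
})

test_that("both beta metrics are proper bounded dissimilarities on random tables", {
  for (seed in 1:5) {
    tbl <- random_rel(7, 10, seed = seed)
    for (met in c("yue_clayton", "bray_curtis")) {
      d <- as.matrix(beta_dissimilarity(tbl, met))
      expect_equal(d, t(d))
      expect_equal(unname(diag(d)), rep(0, 7))
      expect_true(all(d >= 0 & d <= 1 + 1e-12))
    }
    # Yue & Clayton against a direct elementwise oracle
    m <- as.matrix(tbl[-1])
    d <- as.matrix(beta_dissimilarity(tbl, "yue_clayton"))
    for (i in 1:3) {
      for (j in 4:7) {
        a <- m[i, ]; b <- m[j, ]
        expect_equal(d[i, j],
                     1 - sum(a * b) / (sum(a^2) + sum(b^2) - sum(a * b)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("within-group mean distance matches brute-force pair enumeration", {
  tbl <- tibble::tibble(sample_id = c("a", "b", "c"),
                        x = c(0.2, 0.4, 0.8), y = c(0.8, 0.6, 0.2))
  d <- beta_dissimilarity(tbl, "bray_curtis")
  g1 <- tibble::tibble(sample_id = c("a", "b", "c"), group = "g")
  res <- within_group_mean_distance(d, g1)
  expect_equal(res$mean, mean(d$distance))
  expect_equal(res$n_pairs, 3L)

  same <- tibble::tibble(sample_id = c("a", "b"), x = c(0.5, 0.5), y = c(0.5, 0.5))
  res0 <- within_group_mean_distance(
    beta_dissimilarity(same, "bray_curtis"),
    tibble::tibble(sample_id = c("a", "b"), group = "g")
  )
  expect_equal(res0$mean, 0)

  # random table: vectorized result equals a double loop
  tbl2 <- random_rel(8, 6, seed = 3)
  groups <- tibble::tibble(sample_id = tbl2$sample_id,
                           group = rep(c("u", "v"), each = 4))
  d2 <- beta_dissimilarity(tbl2, "bray_curtis")
  dm <- as.matrix(d2)
  res2 <- within_group_mean_distance(d2, groups)
  for (g in c("u", "v")) {
    ids <- groups$sample_id[groups$group == g]
    vals <- c()
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i < j) vals <- c(vals, dm[ids[i], ids[j]])
      }
    }
    expect_equal(res2$mean[res2$group == g], mean(vals))
    expect_equal(res2$sem[res2$group == g], sd(vals) / sqrt(length(vals)))
  }
  expect_error(
    within_group_mean_distance(d2, dplyr::mutate(groups, group = sample_id)),
    "< 2 samples"
  )
})

test_that("PCoA reproduces Euclidean configurations exactly", {
  # points on a line: axis 1 recovers the line up to sign
  pts <- c(0, 1, 3, 7)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  dd <- structure(
    tibble::tibble(
      sample_a = rownames(dm)[row(dm)[upper.tri(dm)]],
      sample_b = colnames(dm)[col(dm)[upper.tri(dm)]],
      distance = dm[upper.tri(dm)]
    ),
    metric = "bray_curtis", sample_ids = rownames(dm),
    class = c("fmn_dist", "tbl_df", "tbl", "data.frame")
  )
  pc <- pcoa_ordination(dd, k = 2)
  ax1 <- pc$coordinates$Axis1
  recovered <- as.matrix(dist(ax1))
  expect_lt(max(abs(recovered - unname(dm))), 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))

  # planar configuration: two axes carry all positive inertia
  withr::with_seed(11, {
    xy <- cbind(runif(6), runif(6))
  })
  dm2 <- as.matrix(dist(xy))
  rownames(dm2) <- colnames(dm2) <- paste0("p", 1:6)
  dd2 <- structure(
    tibble::tibble(
      sample_a = rownames(dm2)[row(dm2)[upper.tri(dm2)]],
      sample_b = colnames(dm2)[col(dm2)[upper.tri(dm2)]],
      distance = dm2[upper.tri(dm2)]
    ),
    metric = "bray_curtis", sample_ids = rownames(dm2),
    class = c("fmn_dist", "tbl_df", "tbl", "data.frame")
  )
  pc2 <- pcoa_ordination(dd2, k = 2)
  expect_equal(sum(pc2$var_explained), 1, tolerance = 1e-8)
  expect_error(pcoa_ordination(dd2, k = 0), "positive")
  expect_error(pcoa_ordination(dd2, k = 6), "smaller")
})
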