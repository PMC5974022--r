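#' Per-sample alpha diversity
#'
#' Computes observed richness (count of taxa with strictly positive
#' abundance) and the Shannon index `H = -sum(p_i * log(p_i))` over the
#' positive proportions of each sample.
#'
#' @param table Abundance tibble (counts or relative).
#' @param base Logarithm base for Shannon; natural log by default, which is
#'   the convention of the upstream 16S tooling.
#' @return Tibble with columns `sample_id`, `observed_taxa`, `shannon`.
#' @examples
#' tbl <- tibble::tibble(sample_id = "s1", a = 1, b = 1, c = 1, d = 1)
#' alpha_diversity(tbl) # shannon = log(4)
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- feature_matrix(table)
  if (any(m < 0)) abort("negative abundances")
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("all-zero row(s): %s",
                  paste(rownames(m)[totals <= 0], collapse = ", ")))
  }
  p <- m / totals
  shannon <- apply(p, 1, function(row) {
    pos <- row[row > 0]
    -sum(pos * log(pos, base = base))
  })
  tibble(sample_id = rownames(m),
         observed_taxa = as.integer(rowSums(m > 0)),
         shannon = unname(shannon))
}

#' Between-sample beta dissimilarity
#'
#' Computes all pairwise dissimilarities between samples of a
#' relative-abundance table using either the Yue & Clayton theta measure,
#' `d(a, b) = 1 - sum(a*b) / (sum(a^2) + sum(b^2) - sum(a*b))`,
#' or Bray-Curtis, `d(a, b) = sum(|a - b|) / sum(a + b)`.
#'
#' @param table Relative-abundance tibble with >= 2 samples.
#' @param metric `"yue_clayton"` or `"bray_curtis"`.
#' @return A long tibble of class `fmn_dist` with columns `sample_a`,
#'   `sample_b` (unordered pairs, a < b in input order) and `distance`;
#'   attributes `metric` and `sample_ids`. Convert with [as.matrix()] or
#'   [stats::as.dist()].
#' @export
beta_dissimilarity <- function(table, metric = c("yue_clayton", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- feature_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  d <- switch(metric,
    bray_curtis = as.matrix(vegan::vegdist(m, method = "bray")),
    yue_clayton = {
      cp <- tcrossprod(m)           # sum_i a_i b_i
      sq <- diag(cp)                # sum_i a_i^2
      denom <- outer(sq, sq, "+") - cp
      dd <- 1 - cp / denom
      diag(dd) <- 0
      dd
    }
  )
  ids <- rownames(m)
  pair <- which(upper.tri(d), arr.ind = TRUE)
  out <- tibble(sample_a = ids[pair[, 1]], sample_b = ids[pair[, 2]],
                distance = d[pair])
  structure(out, metric = metric, sample_ids = ids,
            class = c("fmn_dist", class(out)))
}

#' @export
as.matrix.fmn_dist <- function(x, ...) {
  ids <- attr(x, "sample_ids")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(x$sample_a, ids)
  j <- match(x$sample_b, ids)
  m[cbind(i, j)] <- x$distance
  m[cbind(j, i)] <- x$distance
  m
}

#' @export
as.dist.fmn_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(as.matrix(m), diag = diag, upper = upper)
}

#' Mean within-group distance
#'
#' Mean and standard error of the dissimilarity over all unordered
#' within-group sample pairs (diagonal excluded), as used to compare
#' within-group Bray-Curtis spread between cohorts.
#'
#' @param dist An `fmn_dist` from [beta_dissimilarity()].
#' @param groups Data frame with columns `sample_id` and `group` covering
#'   every sample in `dist`.
#' @return Tibble with `group`, `n_pairs`, `mean`, `sem`.
#' @export
within_group_mean_distance <- function(dist, groups) {
  stopifnot(inherits(dist, "fmn_dist"))
  groups <- as_tibble(groups)
  ids <- attr(dist, "sample_ids")
  missing <- setdiff(ids, groups$sample_id)
  if (length(missing)) {
    abort(sprintf("unlabelled sample(s): %s", paste(missing, collapse = ", ")))
  }
  g <- setNames(as.character(groups$group), groups$sample_id)
  small <- names(which(table(g[ids]) < 2))
  if (length(small)) {
    abort(sprintf("group(s) with < 2 samples: %s", paste(small, collapse = ", ")))
  }
  dist |>
    filter(g[.data$sample_a] == g[.data$sample_b]) |>
    mutate(group = g[.data$sample_a]) |>
    group_by(.data$group) |>
    summarise(n_pairs = dplyr::n(),
              mean = mean(.data$distance),
              sem = stats::sd(.data$distance) / sqrt(dplyr::n()),
              .groups = "drop")
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Double-centres `-0.5 * D^2`, eigendecomposes, and returns the top-`k`
#' positive-eigenvalue axes. The sign of each axis is fixed so that the
#' coordinate with the largest magnitude is positive, making ordinations
#' reproducible across platforms.
#'
#' @param dist An `fmn_dist`.
#' @param k Number of axes (1 <= k < number of samples).
#' @return A list of class `fmn_pcoa` with `coordinates` (tibble:
#'   `sample_id`, `Axis1` ... `Axisk`), `eigenvalues` (all eigenvalues,
#'   non-increasing), and `var_explained` (fraction of positive inertia
#'   per returned axis).
#' @export
pcoa_ordination <- function(dist, k = 2) {
  stopifnot(inherits(dist, "fmn_dist"))
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k <= 0) abort("k must be positive")
  if (k >= n) abort("k must be smaller than the number of samples")
  A <- -0.5 * d^2
  # double-centering: B = A - row means - col means + grand mean
  B <- sweep(A, 1, rowMeans(A))
  B <- sweep(B, 2, colMeans(B))
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-10)
  k_eff <- min(k, length(pos))
  if (k_eff == 0) abort("no positive eigenvalues; degenerate distance matrix")
  coords <- eg$vectors[, pos[seq_len(k_eff)], drop = FALSE] %*%
    diag(sqrt(eg$values[pos[seq_len(k_eff)]]), k_eff)
  for (j in seq_len(k_eff)) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("Axis", seq_len(k_eff))
  structure(list(
    coordinates = bind_cols(tibble(sample_id = rownames(d)),
                            as_tibble(coords)),
    eigenvalues = eg$values,
    var_explained = eg$values[pos[seq_len(k_eff)]] / sum(eg$values[pos])
  ), class = "fmn_pcoa")
}

#' @export
print.fmn_pcoa <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat(sprintf("<fmn_pcoa> %d samples, %d axes (%.1f%% of positive inertia)\n",
              nrow(x$coordinates), k, 100 * sum(x$var_explained)))
  invisible(x)
}

#' @rdname pcoa_ordination
#' @param object An `fmn_pcoa`.
#' @param colour_by Optional data frame (`sample_id`, `group`) to colour
#'   points.
#' @param ... Unused.
#' @method autoplot fmn_pcoa
#' @export
autoplot.fmn_pcoa <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  if (!is.null(colour_by)) {
    df <- left_join(df, as_tibble(colour_by), by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(colour_by)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
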