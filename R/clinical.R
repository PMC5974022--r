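# Feature-to-clinical cross-correlation with FDR control, plus the
# univariate nonparametric group tests.

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min over {j : p_(j) >= p_(i)} of p_(j) * m / rank(j)`, capped at
#' 1. Order-preserving: `q` is a monotone transform of `p`. `p.adjust`
#' implements the same rule and serves as an independent cross-check in
#' the test suite; this direct implementation is kept because the step-up
#' rule is part of the method's contract.
#'
#' @param p Numeric vector of P values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return Vector of adjusted q values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  qv <- rev(cummin(rev(ranked)))
  # cap at 1 and guard the q >= p contract against 1-ulp rounding in p*m/j
  qv <- pmin(pmax(qv, pv[o]), 1)
  q[ok][o] <- qv
  q
}

#' Cross-correlate features with clinical parameters under FDR control
#'
#' Pearson correlation of every (feature, clinical parameter) pair over
#' their shared samples, with pairwise-complete handling of missing
#' clinical values, two-sided t-test P values, and Benjamini-Hochberg
#' adjustment pooled over the full matrix of tests. A pair is starred when
#' `q <= alpha` (inclusive by default, configurable to strict).
#'
#' @param features Sample-by-feature tibble (`sample_id` first).
#' @param clinical Tibble with `sample_id` and numeric parameter columns
#'   (non-numeric columns such as group labels are ignored).
#' @param alpha FDR level for the stars (default 0.05).
#' @param strict Use `q < alpha` instead of `q <= alpha`.
#' @return A long tibble of class `fmn_crosscorr` with columns `feature`,
#'   `parameter`, `n`, `r`, `p`, `q`, `starred`; attribute `alpha`.
#' @export
crosscorrelate <- function(features, clinical, alpha = 0.05, strict = FALSE) {
  fm <- feature_matrix(features)
  clinical <- as_tibble(clinical)
  num_cols <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  cm <- as.matrix(clinical[num_cols])
  rownames(cm) <- as.character(clinical$sample_id)
  shared <- intersect(rownames(fm), rownames(cm))
  if (length(shared) < 3) abort("need at least 3 shared samples")
  fm <- fm[shared, , drop = FALSE]
  cm <- cm[shared, , drop = FALSE]
  const <- apply(cm, 2, function(col) {
    v <- var(col, na.rm = TRUE)
    !is.finite(v) || v == 0
  })
  if (any(const)) {
    warn(sprintf("constant clinical column(s) excluded: %s",
                 paste(colnames(cm)[const], collapse = ", ")))
    cm <- cm[, !const, drop = FALSE]
  }
  if (ncol(cm) == 0) abort("no usable clinical columns")
  r <- suppressWarnings(cor(fm, cm, use = "pairwise.complete.obs"))
  n_eff <- crossprod(!is.na(fm) * 1, !is.na(cm) * 1)
  tstat <- r * sqrt(pmax(n_eff - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = pmax(n_eff - 2, 1), lower.tail = FALSE)
  p[n_eff < 3] <- NA
  q <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  out <- tibble(
    feature = rep(rownames(r), times = ncol(r)),
    parameter = rep(colnames(r), each = nrow(r)),
    n = as.integer(as.vector(n_eff)),
    r = as.vector(r), p = as.vector(p), q = as.vector(q)
  ) |>
    mutate(starred = !is.na(.data$q) &
             (if (strict) .data$q < alpha else .data$q <= alpha))
  structure(out, alpha = alpha, class = c("fmn_crosscorr", class(out)))
}

#' @rdname crosscorrelate
#' @param object An `fmn_crosscorr`.
#' @param ... Unused.
#' @method autoplot fmn_crosscorr
#' @export
autoplot.fmn_crosscorr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$parameter, .data$feature,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$starred),
                        shape = 8, colour = "white", size = 2) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Wide matrices from a cross-correlation result
#' @param x An `fmn_crosscorr`.
#' @param value One of `"r"`, `"p"`, `"q"`.
#' @return Feature-by-parameter matrix.
#' @export
crosscorr_matrix <- function(x, value = c("r", "p", "q")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(x[c("feature", "parameter", value)],
                             names_from = "parameter", values_from = all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$feature
  m
}

#' Nonparametric group comparison per feature
#'
#' Mann-Whitney U (exactly two groups) or Kruskal-Wallis (two or more)
#' test per feature column, as used for the univariate metabolite and
#' abundance comparisons. For the Mann-Whitney test the exact null
#' distribution is used when both groups have fewer than 50 observations
#' and there are no ties; otherwise the normal approximation with
#' continuity correction applies (the `stats::wilcox.test` switch).
#'
#' @param features Sample-by-feature tibble.
#' @param groups Data frame (`sample_id`, `group`).
#' @param test `"mann_whitney"` or `"kruskal_wallis"`.
#' @return Tibble with `feature`, `statistic`, `p`.
#' @export
group_compare <- function(features, groups,
                          test = c("mann_whitney", "kruskal_wallis")) {
  test <- match.arg(test)
  m <- feature_matrix(features)
  g <- setNames(as.character(groups$group), groups$sample_id)[rownames(m)]
  if (anyNA(g)) abort("every sample needs a group label")
  tab <- table(g)
  if (any(tab == 0) || length(tab) < 2) abort("need at least 2 non-empty groups")
  if (test == "mann_whitney" && length(tab) != 2) {
    abort("mann_whitney requires exactly 2 groups")
  }
  res <- lapply(colnames(m), function(f) {
    x <- m[, f]
    if (test == "mann_whitney") {
      lev <- names(tab)
      ht <- suppressWarnings(wilcox.test(x[g == lev[1]], x[g == lev[2]],
                                         alternative = "two.sided"))
      tibble(feature = f, statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      ht <- kruskal.test(x, factor(g))
      tibble(feature = f, statistic = unname(ht$statistic), p = ht$p.value)
    }
  })
  bind_rows(res)
}
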