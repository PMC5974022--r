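# Functional metagenomic network (FMN) construction: merged taxon +
# metabolite features -> thresholded signed Pearson co-occurrence graph ->
# Louvain communities (FMCs), betweenness keystones and descriptor tables.

#' Merge taxon and metabolite features into one sample-by-feature matrix
#'
#' Column-concatenates a (filtered, relative) taxon table and a metabolite
#' bucket table over their shared samples, tagging each feature with its
#' kind. If the sample sets differ, the intersection is used with a
#' warning; an empty intersection is an error.
#'
#' @param taxa Relative-abundance tibble (`sample_id` + taxon columns),
#'   typically after [filter_by_mean_abundance()].
#' @param metabolites Bucket-matrix or labelled metabolite tibble.
#' @return A tibble of class `fmn_features` (`sample_id` + feature
#'   columns) with attributes `kind` (named character: "taxon" /
#'   "metabolite") and `mean_rel_abund` (named numeric; `NA` for
#'   metabolites).
#' @export
merge_features <- function(taxa, metabolites) {
  mt <- feature_matrix(taxa)
  mm <- feature_matrix(metabolites)
  shared <- intersect(rownames(mt), rownames(mm))
  if (length(shared) == 0) abort("no shared samples between taxa and metabolites")
  if (length(shared) < max(nrow(mt), nrow(mm))) {
    warn(sprintf("sample sets differ; using the %d shared samples", length(shared)))
  }
  dup <- intersect(colnames(mt), colnames(mm))
  if (length(dup)) {
    abort(sprintf("feature ids present in both tables: %s", paste(dup, collapse = ", ")))
  }
  m <- cbind(mt[shared, , drop = FALSE], mm[shared, , drop = FALSE])
  out <- matrix_to_tbl(m)
  attr(out, "kind") <- setNames(
    c(rep("taxon", ncol(mt)), rep("metabolite", ncol(mm))), colnames(m))
  attr(out, "mean_rel_abund") <- setNames(
    c(colMeans(mt[shared, , drop = FALSE]), rep(NA_real_, ncol(mm))), colnames(m))
  class(out) <- c("fmn_features", class(out))
  out
}

feature_meta <- function(features) {
  m <- feature_matrix(features)
  ids <- colnames(m)
  kind <- attr(features, "kind") %||% setNames(rep("feature", length(ids)), ids)
  mra <- attr(features, "mean_rel_abund") %||% setNames(rep(NA_real_, length(ids)), ids)
  tibble(feature = ids, kind = unname(kind[ids]),
         mean_rel_abund = unname(mra[ids]))
}

#' Pairwise Pearson correlation with P values
#'
#' Sample Pearson correlations between all feature pairs, with two-sided P
#' values from the t distribution on `n - 2` degrees of freedom. Constant
#' features yield `NA` entries and a warning.
#'
#' @param features Sample-by-feature tibble (e.g. from [merge_features()]).
#' @return List with `r` and `p` (symmetric matrices, unit / zero
#'   diagonal) and `n` (sample count).
#' @export
pearson_matrix <- function(features) {
  m <- feature_matrix(features)
  n <- nrow(m)
  if (n < 3) abort("need at least 3 samples for correlation")
  const <- apply(m, 2, function(col) var(col) == 0 || !is.finite(var(col)))
  if (any(const)) {
    warn(sprintf("constant feature(s) give undefined correlations: %s",
                 paste(colnames(m)[const], collapse = ", ")))
  }
  r <- suppressWarnings(cor(m))
  diag(r) <- ifelse(const, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- ifelse(const, NA_real_, 0)
  list(r = r, p = p, n = n)
}

#' Build a thresholded signed co-occurrence network
#'
#' Creates an edge for every unordered feature pair whose Pearson
#' coefficient strictly exceeds `threshold` (synergistic) or falls
#' strictly below `-threshold` (competitive), matching the
#' published `-0.7 > r > 0.7` rule. Undefined correlations never create
#' edges; isolated nodes are retained.
#'
#' @param corr Result of [pearson_matrix()] (or a correlation matrix).
#' @param features The `fmn_features` tibble the correlations came from
#'   (used for kind tags, mean abundances and co-occurrence counts).
#' @param threshold Absolute correlation threshold in (0, 1); default 0.7.
#' @param p_max Optional additional P-value filter (default `NULL`: the
#'   edge set is r-thresholded only).
#' @return An object of class `fmn_network`: list with `nodes` (tibble:
#'   feature, kind, mean_rel_abund, degree, betweenness, community),
#'   `edges` (tibble: from, to, r, sign, cooccurrence) and `threshold`.
#'   Degree and betweenness are filled in by [node_metrics()], which is
#'   called automatically.
#' @export
build_network <- function(corr, features, threshold = 0.7, p_max = NULL) {
  if (is.list(corr) && !is.null(corr$r)) {
    R <- corr$r
    P <- corr$p
  } else {
    R <- corr
    P <- NULL
  }
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  m <- feature_matrix(features)
  ids <- colnames(R)
  stopifnot(identical(ids, colnames(m)))
  nodes <- feature_meta(features) |>
    mutate(degree = 0L, betweenness = 0, community = NA_integer_)
  pair <- which(upper.tri(R), arr.ind = TRUE)
  rv <- R[pair]
  keep <- !is.na(rv) & abs(rv) > threshold
  if (!is.null(p_max) && !is.null(P)) keep <- keep & !is.na(P[pair]) & P[pair] <= p_max
  pair <- pair[keep, , drop = FALSE]
  rv <- rv[keep]
  nz <- m > 0
  cooc <- vapply(seq_len(nrow(pair)), function(k) {
    sum(nz[, pair[k, 1]] & nz[, pair[k, 2]])
  }, numeric(1))
  edges <- tibble(
    from = ids[pair[, 1]], to = ids[pair[, 2]], r = rv,
    sign = ifelse(rv > 0, "synergistic", "competitive"),
    cooccurrence = as.integer(cooc)
  )
  net <- structure(list(nodes = nodes, edges = edges, threshold = threshold),
                   class = "fmn_network")
  node_metrics(net)
}

as_igraph <- function(net, weighted = FALSE) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("from", "to", "r", "sign", "cooccurrence")],
    directed = FALSE, vertices = net$nodes["feature"]
  )
  if (weighted) igraph::E(g)$weight <- abs(igraph::E(g)$r)
  g
}

#' Degree and betweenness centrality of network nodes
#'
#' Degree is the incident-edge count; betweenness is the unnormalized
#' Brandes value on the unweighted thresholded graph (the sum over
#' unordered node pairs of the fraction of shortest paths passing through
#' the node). Disconnected components are handled natively. A
#' weighted-shortest-path variant (weights `1/|r|`) is available behind
#' `weighted = TRUE`.
#'
#' @param net An `fmn_network`.
#' @param weighted Use `1/|r|` edge lengths for shortest paths.
#' @return The network with its `nodes` table updated.
#' @export
node_metrics <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "fmn_network"))
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- if (weighted && nrow(net$edges) > 0) {
    igraph::betweenness(g, weights = 1 / abs(igraph::E(g)$r), normalized = FALSE)
  } else {
    igraph::betweenness(g, weights = NA, normalized = FALSE)
  }
  idx <- match(net$nodes$feature, igraph::V(g)$name)
  net$nodes$degree <- as.integer(deg[idx])
  net$nodes$betweenness <- unname(btw[idx])
  net
}

#' Detect functional metagenomic communities (FMCs)
#'
#' Louvain community detection maximizing the weighted modularity
#' `Q = (1/2m) * sum_ij (w_ij - gamma k_i k_j / 2m) delta(c_i, c_j)` with
#' edge weights `w_ij = |r|`, at a configurable resolution `gamma`
#' (default 1). The node visit order is randomized per restart from the
#' seed and the best-of-restarts partition is returned; the reported
#' modularity is the Q of that partition. Isolated nodes form singleton
#' communities.
#'
#' @param net An `fmn_network` with at least one edge.
#' @param resolution Resolution parameter gamma.
#' @param seed RNG seed controlling the restarts.
#' @param n_restarts Number of randomized restarts (default 20).
#' @return A tibble of class `fmn_partition` (`feature`, `community`;
#'   labels contiguous from 0, ordered by decreasing community size) with
#'   attributes `modularity`, `resolution`, `seed`, `n_restarts`.
#' @export
detect_fmcs <- function(net, resolution = 1, seed = 1L, n_restarts = 20) {
  stopifnot(inherits(net, "fmn_network"))
  if (nrow(net$edges) == 0) abort("community detection needs at least one edge")
  g <- as_igraph(net, weighted = TRUE)
  n <- igraph::vcount(g)
  best <- NULL
  best_q <- -Inf
  with_seed(seed, {
    for (i in seq_len(n_restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                    resolution = resolution)
      memb <- igraph::membership(cl)[igraph::V(g)$name]
      q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                              resolution = resolution)
      if (q > best_q) {
        best_q <- q
        best <- memb
      }
    }
  })
  # relabel contiguous from 0, largest community first, ties by first feature
  sizes <- sort(table(best), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- tibble(feature = igraph::V(g)$name,
                community = unname(relabel[as.character(best)]))
  structure(out, modularity = best_q, resolution = resolution,
            seed = seed, n_restarts = n_restarts,
            class = c("fmn_partition", class(out)))
}

#' Apply a partition to a network
#' @param net An `fmn_network`.
#' @param partition An `fmn_partition`.
#' @return The network with the `community` node column filled in.
#' @export
set_communities <- function(net, partition) {
  idx <- match(net$nodes$feature, partition$feature)
  net$nodes$community <- as.integer(partition$community[idx])
  net
}

#' Network descriptor summary (Table-style record)
#'
#' Computes the descriptor record used in the study's network tables:
#' node/edge counts, synergistic and competitive edge counts and
#' percentages, the synergistic/competitive ratio, graph density
#' `2E/(N(N-1))`, modularity, community count, and the top-`keystone_k`
#' keystone features by betweenness centrality (ties broken by higher mean
#' relative abundance, then lexical id). Keystones are reported jointly
#' and within separate taxon / metabolite pools.
#'
#' @param net An `fmn_network` with metrics computed.
#' @param partition Optional `fmn_partition` (for modularity and FMC
#'   membership of keystones).
#' @param keystone_k Number of keystones to report (default 5).
#' @param digits Named rounding precision for the printed record
#'   (`pct`, `ratio`, `density`, `modularity`).
#' @return An object of class `fmn_summary`: list with one-row tibble
#'   `stats`, tibble `keystones` and list `keystones_by_kind`.
#' @export
network_summary <- function(net, partition = NULL, keystone_k = 5,
                            digits = c(pct = 1, ratio = 2, density = 3,
                                       modularity = 3)) {
  stopifnot(inherits(net, "fmn_network"))
  N <- nrow(net$nodes)
  if (N < 2) abort("summary needs at least 2 nodes")
  E <- nrow(net$edges)
  n_syn <- sum(net$edges$sign == "synergistic")
  n_com <- E - n_syn
  if (!is.null(partition)) net <- set_communities(net, partition)
  ranked <- net$nodes |>
    arrange(desc(.data$betweenness),
            desc(dplyr::coalesce(.data$mean_rel_abund, -Inf)), .data$feature)
  stats <- tibble(
    n_nodes = N, n_edges = E, n_synergistic = n_syn, n_competitive = n_com,
    pct_synergistic = if (E > 0) round(100 * n_syn / E, digits[["pct"]]) else NA_real_,
    pct_competitive = if (E > 0) round(100 * n_com / E, digits[["pct"]]) else NA_real_,
    syn_com_ratio = if (n_com > 0) round(n_syn / n_com, digits[["ratio"]]) else NA_real_,
    density = round(graph_density(N, E), digits[["density"]]),
    modularity = if (!is.null(partition)) {
      round(attr(partition, "modularity"), digits[["modularity"]])
    } else NA_real_,
    n_communities = if (!is.null(partition)) {
      length(unique(partition$community))
    } else NA_integer_
  )
  structure(list(
    stats = stats,
    keystones = head(ranked, keystone_k),
    keystones_by_kind = lapply(
      split(ranked, ranked$kind),
      function(df) head(df, keystone_k)
    )
  ), class = "fmn_summary")
}

#' @export
print.fmn_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<fmn_summary> %d nodes, %d edges (syn %d / com %d, ratio %s), density %s, modularity %s\n",
              s$n_nodes, s$n_edges, s$n_synergistic, s$n_competitive,
              format(s$syn_com_ratio), format(s$density), format(s$modularity)))
  cat("keystones:", paste(x$keystones$feature, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fmn_network <- function(x, ...) {
  cat(sprintf("<fmn_network> %d nodes, %d edges, |r| > %s\n",
              nrow(x$nodes), nrow(x$edges), format(x$threshold)))
  invisible(x)
}

#' Internal clustering validation of a partition
#'
#' Silhouette and Calinski-Harabasz scores of a feature partition on the
#' correlation-distance embedding (`d = 1 - r`). The silhouette is
#' computed directly on the distances; Calinski-Harabasz on a classical
#' MDS embedding of the same distances.
#'
#' @param R Feature correlation matrix.
#' @param partition An `fmn_partition` (or data frame feature/community)
#'   with >= 2 communities.
#' @return Tibble with `silhouette` (mean width, in `[-1, 1]`) and
#'   `calinski_harabasz`.
#' @export
validate_partition <- function(R, partition) {
  feats <- intersect(partition$feature, colnames(R))
  labels <- setNames(partition$community, partition$feature)[feats]
  if (length(unique(labels)) < 2) abort("validation needs >= 2 communities")
  d <- 1 - R[feats, feats]
  diag(d) <- 0
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  emb <- suppressWarnings(cmdscale(stats::as.dist(d),
                                   k = max(1, min(length(feats) - 2, 10))))
  ch <- calinski_harabasz(emb, labels)
  tibble(silhouette = mean(sil[, "sil_width"]), calinski_harabasz = ch)
}

# CH = [trace(B)/(k-1)] / [trace(W)/(n-k)] on a Euclidean embedding
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  k <- length(unique(labels))
  centroid <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - centroid)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @method tidy fmn_network
#' @export
tidy.fmn_network <- function(x, ...) x$edges

#' @method glance fmn_network
#' @export
glance.fmn_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_synergistic = sum(x$edges$sign == "synergistic"),
         n_competitive = sum(x$edges$sign == "competitive"),
         density = graph_density(max(nrow(x$nodes), 2), nrow(x$edges)),
         threshold = x$threshold)
}

#' @rdname detect_fmcs
#' @param x An `fmn_partition`.
#' @param ... Unused.
#' @method glance fmn_partition
#' @export
glance.fmn_partition <- function(x, ...) {
  tibble(n_communities = length(unique(x$community)),
         modularity = attr(x, "modularity"),
         resolution = attr(x, "resolution"),
         seed = attr(x, "seed"), n_restarts = attr(x, "n_restarts"))
}

#' Plot network node metrics
#'
#' Degree vs betweenness scatter, coloured by community, sized by mean
#' relative abundance -- a metric-level view of the network (layout-based
#' rendering is out of scope).
#'
#' @param object An `fmn_network`.
#' @param ... Unused.
#' @method autoplot fmn_network
#' @export
autoplot.fmn_network <- function(object, ...) {
  ggplot2::ggplot(object$nodes,
                  ggplot2::aes(.data$degree, .data$betweenness)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$community),
                                     shape = .data$kind), size = 2) +
    ggplot2::labs(colour = "FMC", shape = NULL,
                  x = "degree", y = "betweenness centrality") +
    ggplot2::theme_minimal()
}
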