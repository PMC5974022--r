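test_that("feature merging tags kinds and harmonizes samples", {
  taxa <- tibble::tibble(sample_id = paste0("s", 1:5),
                         t1 = runif(5), t2 = runif(5), t3 = runif(5))
  mets <- tibble::tibble(sample_id = paste0("s", 1:5),
                         m1 = runif(5), m2 = runif(5))
  mg <- merge_features(taxa, mets)
  expect_equal(dim(mg), c(5, 6))
  expect_equal(unname(attr(mg, "kind")), c("taxon", "taxon", "taxon",
                                           "metabolite", "metabolite"))
  expect_equal(attr(mg, "mean_rel_abund")[["t1"]], mean(taxa$t1))
  expect_true(is.na(attr(mg, "mean_rel_abund")[["m1"]]))

  expect_error(
    merge_features(taxa, dplyr::mutate(mets, sample_id = paste0("x", 1:5))),
    "no shared"
  )
  expect_warning(
    mg4 <- merge_features(taxa, mets[1:4, ]),
    "shared"
  )
  expect_equal(nrow(mg4), 4)
})

test_that("Pearson matrices match the textbook formula and cor.test p values", {
  withr::with_seed(10, {
    tbl <- tibble::as_tibble(matrix(rnorm(60), 10, 6),
                             .name_repair = ~ paste0("f", 1:6)) |>
      dplyr::mutate(sample_id = paste0("s", 1:10), .before = 1)
  })
  got <- pearson_matrix(tbl)
  m <- as.matrix(tbl[-1])
  for (i in 1:5) {
    for (j in (i + 1):6) {
      x <- m[, i]; y <- m[, j]
      r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(got$r[i, j], r_oracle, tolerance = 1e-12)
      ct <- cor.test(x, y)
      expect_equal(got$p[i, j], ct$p.value, tolerance = 1e-12)
    }
  }
  # exact linear relations
  lin <- tibble::tibble(sample_id = paste0("s", 1:6), x = 1:6,
                        y = 2 * (1:6) + 1, z = -(1:6))
  R <- pearson_matrix(lin)$r
  expect_equal(R["x", "y"], 1)
  expect_equal(R["x", "z"], -1)

  expect_warning(pearson_matrix(
    tibble::tibble(sample_id = paste0("s", 1:5), a = 1:5, b = rep(2, 5))
  ), "constant")
  expect_error(pearson_matrix(tbl[1:2, ]), "3 samples")
})

test_that("network edges obey the strict threshold and sign classification", {
  R <- matrix(c(1, 0.8, -0.75,
                0.8, 1, 0.1,
                -0.75, 0.1, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  feats <- tibble::tibble(sample_id = paste0("s", 1:4),
                          a = c(1, 0, 2, 3), b = c(2, 1, 0, 4), c = c(5, 2, 1, 0))
  net <- build_network(R, feats)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("synergistic", "competitive"))
  # co-occurrence counts samples where both features are non-zero
  ab <- net$edges[net$edges$sign == "synergistic", ]
  expect_equal(ab$cooccurrence, 2L)

  # r exactly at the threshold: no edge (strict inequality)
  R2 <- R; R2["a", "b"] <- R2["b", "a"] <- 0.7
  net2 <- build_network(R2, feats)
  expect_equal(net2$edges$sign, "competitive")

  # all sub-threshold: isolated nodes retained
  R3 <- diag(3); dimnames(R3) <- dimnames(R)
  net3 <- build_network(R3, feats)
  expect_equal(nrow(net3$edges), 0)
  expect_equal(nrow(net3$nodes), 3)
  expect_equal(net3$nodes$degree, rep(0L, 3))

  expect_error(build_network(R, feats, threshold = 1.2), "threshold")
  # undefined correlations never create edges
  R4 <- R; R4["a", "b"] <- R4["b", "a"] <- NA
  expect_equal(nrow(build_network(R4, feats)$edges), 1)
})

test_that("degree and betweenness match closed forms", {
  path <- structure(list(
    nodes = tibble::tibble(feature = c("A", "B", "C"), kind = "taxon",
                           mean_rel_abund = NA_real_, degree = 0L,
                           betweenness = 0, community = NA_integer_),
    edges = tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                           r = 0.9, sign = "synergistic", cooccurrence = 1L),
    threshold = 0.7
  ), class = "fmn_network")
  pm <- node_metrics(path)
  expect_equal(pm$nodes$betweenness, c(0, 1, 0))
  expect_equal(pm$nodes$degree, c(1L, 2L, 1L))

  star <- structure(list(
    nodes = tibble::tibble(feature = c("hub", paste0("l", 1:4)), kind = "taxon",
                           mean_rel_abund = NA_real_, degree = 0L,
                           betweenness = 0, community = NA_integer_),
    edges = tibble::tibble(from = "hub", to = paste0("l", 1:4),
                           r = 0.9, sign = "synergistic", cooccurrence = 1L),
    threshold = 0.7
  ), class = "fmn_network")
  sm <- node_metrics(star)
  expect_equal(sm$nodes$betweenness[1], 6) # C(4,2) leaf pairs
  expect_equal(sm$nodes$degree[1], 4L)
})

test_that("betweenness equals exhaustive shortest-path enumeration on random graphs", {
  for (seed in 1:30) {
    n <- sample(4:12, 1)
    net <- random_network(n, p_edge = 0.35, seed = seed)
    oracle <- brute_betweenness(net$edges, net$nodes$feature)
    expect_equal(net$nodes$betweenness, unname(oracle[net$nodes$feature]),
                 tolerance = 1e-10)
  }
})

test_that("Louvain modularity matches closed forms on triangle graphs", {
  tri2 <- structure(list(
    nodes = tibble::tibble(feature = letters[1:6], kind = "taxon",
                           mean_rel_abund = NA_real_, degree = 0L,
                           betweenness = 0, community = NA_integer_),
    edges = tibble::tibble(
      from = c("a", "b", "c", "d", "e", "f"),
      to = c("b", "c", "a", "e", "f", "d"),
      r = 1, sign = "synergistic", cooccurrence = 1L
    ),
    threshold = 0.7
  ), class = "fmn_network")
  part <- detect_fmcs(tri2, seed = 1)
  expect_equal(length(unique(part$community)), 2)
  # two disconnected unit triangles: Q = 2 * (3/6 - (6/12)^2) = 0.5
  expect_equal(attr(part, "modularity"), 0.5, tolerance = 1e-12)

  tri1 <- tri2
  tri1$nodes <- tri1$nodes[1:3, ]
  tri1$edges <- tri1$edges[1:3, ]
  p1 <- detect_fmcs(tri1, seed = 1)
  expect_equal(length(unique(p1$community)), 1)
  expect_equal(attr(p1, "modularity"), 0, tolerance = 1e-12)

  empty <- tri1
  empty$edges <- tri1$edges[0, ]
  expect_error(detect_fmcs(empty, seed = 1), "edge")
})

test_that("the returned partition dominates trivial partitions in modularity", {
  for (seed in c(2, 5)) {
    net <- random_network(10, p_edge = 0.4, seed = seed)
    if (nrow(net$edges) == 0) next
    part <- detect_fmcs(net, seed = seed)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes["feature"])
    w <- abs(net$edges$r)
    q_single <- igraph::modularity(g, seq_len(10), weights = w)
    q_one <- igraph::modularity(g, rep(1, 10), weights = w)
    expect_gte(attr(part, "modularity"), q_single - 1e-12)
    expect_gte(attr(part, "modularity"), q_one - 1e-12)
  }
})

test_that("community detection is deterministic for a fixed seed", {
  net <- random_network(12, p_edge = 0.3, seed = 7)
  p1 <- detect_fmcs(net, seed = 42, n_restarts = 5)
  p2 <- detect_fmcs(net, seed = 42, n_restarts = 5)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(attr(p1, "modularity"), attr(p2, "modularity"))
})

test_that("network summaries reproduce descriptor arithmetic and keystone ties", {
  net <- mock_network(20, n_syn = 30, n_com = 10)
  part <- detect_fmcs(net, seed = 1)
  s <- network_summary(net, part)$stats
  expect_equal(s$n_synergistic + s$n_competitive, s$n_edges)
  expect_equal(s$density, round(2 * 40 / (20 * 19), 3))
  expect_equal(s$syn_com_ratio, 3)
  expect_equal(s$pct_synergistic, 75)
  expect_equal(s$pct_synergistic + s$pct_competitive, 100)

  # keystone ties break by mean relative abundance, then id
  net2 <- mock_network(6, n_syn = 5, n_com = 0)
  net2$nodes$betweenness <- c(5, 5, 5, 1, 0, 0)
  net2$nodes$mean_rel_abund <- c(0.01, 0.03, 0.02, 0.1, 0.1, 0.1)
  ks <- network_summary(net2, keystone_k = 3)$keystones
  expect_equal(ks$feature, c("f002", "f003", "f001"))

  expect_error(network_summary(mock_network(2, 1, 0)[c("edges", "threshold")]))
})

test_that("partition validation separates planted blocks from random labels", {
  # two perfectly correlated blocks: silhouette tends to 1
  blocks <- rep(1:2, each = 5)
  R <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.999, 0.001))
  diag(R) <- 1
  ids <- paste0("f", 1:10)
  dimnames(R) <- list(ids, ids)
  part <- tibble::tibble(feature = ids, community = blocks)
  v <- validate_partition(R, part)
  expect_gt(v$silhouette, 0.95)

  # random labels on structureless data: |silhouette| small on average
  sils <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      m <- matrix(rnorm(30 * 12), 30, 12)
      colnames(m) <- paste0("g", 1:12)
      Rn <- cor(m)
      labs <- sample(rep(1:2, each = 6))
      validate_partition(Rn, tibble::tibble(feature = colnames(m),
                                            community = labs))$silhouette
    })
  }, numeric(1))
  expect_lt(mean(abs(sils)), 0.2)

  # CH score: true planted partition beats random relabellings
  ch_true <- v$calinski_harabasz
  ch_rand <- vapply(1:50, function(s) {
    labs <- withr::with_seed(s, sample(blocks))
    # skip draws that reproduce the planted partition up to label swap
    if (all(labs == blocks) || all(labs == 3 - blocks)) return(NA_real_)
    validate_partition(R, tibble::tibble(feature = ids,
                                         community = labs))$calinski_harabasz
  }, numeric(1))
  expect_true(all(ch_true > ch_rand, na.rm = TRUE))

  expect_error(validate_partition(R, tibble::tibble(feature = ids, community = 1)),
               "2 communities")
})

test_that("networks round-trip losslessly through every export format", {
  net <- random_network(8, p_edge = 0.5, seed = 3)
  part <- detect_fmcs(net, seed = 1)
  net <- set_communities(net, part)
  net$nodes$mean_rel_abund <- c(0.01, 0.02, NA, NA, 0.05, NA, 0.005, 0.3)

  for (fmt in c("graphml", "gexf", "edge_tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes),
                 tolerance = 1e-12)
    expect_equal(as.data.frame(back$edges), as.data.frame(net$edges),
                 tolerance = 1e-12)
    expect_equal(back$threshold, net$threshold)
  }
  expect_error(export_network(net, tempfile(), "dot"))
  # sign attribute always consistent with r
  expect_true(all((net$edges$r > 0) == (net$edges$sign == "synergistic")))
})
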