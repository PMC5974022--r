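# Shared fixtures and pipeline shortcuts for the test suite. Everything is
# generated in code; no binary fixtures.

# Small relative-abundance tibble with fixed values.
tiny_rel <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    t1 = c(0.5, 0.25, 0.4),
    t2 = c(0.5, 0.75, 0.6)
  )
}

# Random relative-abundance table.
random_rel <- function(n = 6, p = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(n * p), n, p)
    m <- m / rowSums(m)
    colnames(m) <- paste0("t", seq_len(p))
    tibble::as_tibble(m) |>
      dplyr::mutate(sample_id = paste0("s", seq_len(n)), .before = 1)
  })
}

# The standard recovery conditions: two planted blocks at high block
# correlation and low noise, case arm of the default cohort sizes.
recovery_cohort <- function(seed, n_blocks = 2) {
  generate_cohort(cohort_spec(seed = seed, block_corr = 0.95,
                              noise_sd = 0.05, n_blocks = n_blocks))
}

# Case-arm FMN for a cohort: rarefaction -> relative -> 0.5% filter,
# NMR total-integral + PQN + informative-bucket selection, merge, network.
case_network <- function(coh, seed = 1, threshold = 0.7) {
  cl <- coh$clinical
  ids <- cl$sample_id[cl$group == "case"]
  rel <- to_relative(suppressWarnings(
    rarefy_counts(coh$counts, depth = 3101, seed = seed)))
  filt <- filter_by_mean_abundance(rel)
  nmr <- select_informative_buckets(
    pqn_normalize(total_integral_normalize(coh$nmr)))
  merged <- merge_features(filt[filt$sample_id %in% ids, ],
                           nmr[nmr$sample_id %in% ids, ])
  build_network(pearson_matrix(merged), merged, threshold = threshold)
}

# Planted-block recovery for one seed: ARI of the detected FMC partition
# against planted block labels (keystones excluded: they belong to two
# blocks by construction) plus the fraction of planted keystones in the
# top-5 betweenness ranking.
recover_one <- function(seed, n_blocks = 2) {
  coh <- recovery_cohort(seed, n_blocks = n_blocks)
  net <- case_network(coh, seed = seed)
  part <- detect_fmcs(net, seed = seed)
  truth <- coh$truth$block_of_feature
  ks <- coh$truth$keystone_ids
  nonks <- part$feature[!part$feature %in% ks]
  blk <- stats::setNames(truth$block, truth$feature)[nonks]
  summ <- network_summary(net, part)
  c(
    ari = mclust::adjustedRandIndex(part$community[match(nonks, part$feature)], blk),
    keystone_top5 = mean(ks %in% summ$keystones$feature)
  )
}

# Cohort for the HE-consensus recovery example: one strong planted feature
# (generating beta +2 on met05), nine independent null metabolites.
he_recovery_cohort <- function(seed, he_beta = c(met05 = 2)) {
  generate_cohort(cohort_spec(
    n_cases = 100, n_controls = 100, n_taxa = 2, n_metabolites = 10,
    n_blocks = 12, n_keystones = 0, he_beta = he_beta, seed = seed
  ))
}

he_feature_table <- function(coh) {
  standardize_features(select_informative_buckets(
    pqn_normalize(coh$nmr, enforce_total = FALSE)))
}

# Build an fmn_network directly from node/edge counts (for descriptor
# arithmetic tests); r magnitudes are arbitrary above threshold.
mock_network <- function(n_nodes, n_syn, n_com) {
  ids <- sprintf("f%03d", seq_len(n_nodes))
  pairs <- utils::combn(ids, 2)
  n_e <- n_syn + n_com
  stopifnot(n_e <= ncol(pairs))
  edges <- tibble::tibble(
    from = pairs[1, seq_len(n_e)], to = pairs[2, seq_len(n_e)],
    r = c(rep(0.8, n_syn), rep(-0.8, n_com)),
    sign = c(rep("synergistic", n_syn), rep("competitive", n_com)),
    cooccurrence = 1L
  )
  nodes <- tibble::tibble(feature = ids, kind = "taxon",
                          mean_rel_abund = 0.01, degree = 0L,
                          betweenness = 0, community = NA_integer_)
  node_metrics(structure(list(nodes = nodes, edges = edges, threshold = 0.7),
                         class = "fmn_network"))
}

# Exhaustive shortest-path betweenness oracle (Brandes-free): enumerates
# all shortest paths between every node pair by breadth-first layering.
brute_betweenness <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  count_paths <- function(s, t) {
    # all shortest s-t paths via BFS parent sets
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    nsp <- stats::setNames(rep(0, length(nodes)), nodes)
    through <- stats::setNames(rep(list(stats::setNames(
      numeric(length(nodes)), nodes)), length(nodes)), nodes)
    dist[s] <- 0; nsp[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) {
            nsp[w] <- nsp[w] + nsp[v]
            through[[w]] <- through[[w]] + through[[v]]
            if (v != s) through[[w]][v] <- through[[w]][v] + nsp[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    if (is.infinite(dist[t]) || nsp[t] == 0) return(NULL)
    through[[t]] / nsp[t]
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i < j) {
        contrib <- count_paths(nodes[i], nodes[j])
        if (!is.null(contrib)) bc <- bc + contrib
      }
    }
  }
  bc
}

# Random simple graph as an fmn_network (for oracle comparisons).
random_network <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("v%02d", seq_len(n))
    pairs <- utils::combn(ids, 2)
    keep <- stats::runif(ncol(pairs)) < p_edge
    r <- stats::runif(sum(keep), 0.71, 0.99) *
      sample(c(-1, 1), sum(keep), replace = TRUE)
    edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                            r = r,
                            sign = ifelse(r > 0, "synergistic", "competitive"),
                            cooccurrence = 1L)
    nodes <- tibble::tibble(feature = ids, kind = "taxon",
                            mean_rel_abund = NA_real_, degree = 0L,
                            betweenness = 0, community = NA_integer_)
    node_metrics(structure(list(nodes = nodes, edges = edges, threshold = 0.7),
                           class = "fmn_network"))
  })
}
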