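# End-to-end orchestration: one config object, fixed seeds, a run
# directory with every stage output and a manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the integrated pipeline with the study's
#' printed settings as defaults: 0.5% mean-abundance filter, |r| > 0.7
#' edges, Louvain resolution 1, alpha = 0.05, 0.02 ppm buckets, total
#' integral 1000. Inputs are either a [cohort_spec()] (`synthetic`) or
#' paths to the three tables.
#'
#' @param synthetic Optional [cohort_spec()]; when given, inputs are
#'   simulated.
#' @param counts_path,nmr_path,clinical_path Input table paths (TSV/CSV,
#'   `sample_id` first column; `#` comments allowed). Ignored when
#'   `synthetic` is given.
#' @param out_dir Run directory.
#' @param rarefy_depth Rarefaction depth (`NULL` = minimum sample total).
#' @param filter_threshold Mean relative-abundance filter (fraction).
#' @param corr_threshold Network |r| threshold.
#' @param resolution,n_restarts Louvain settings.
#' @param keystone_k Keystones per summary.
#' @param alpha FDR level for cross-correlation stars.
#' @param nmr_total Total-integral target.
#' @param nmr_min_cv CV threshold of [select_informative_buckets()].
#' @param he Named list of [fit_he_consensus()] hyperparameters.
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `fmn_config`.
#' @export
pipeline_config <- function(synthetic = NULL, counts_path = NULL,
                            nmr_path = NULL, clinical_path = NULL,
                            out_dir = tempfile("fmn_run_"),
                            rarefy_depth = NULL, filter_threshold = 0.005,
                            corr_threshold = 0.7, resolution = 1,
                            n_restarts = 20, keystone_k = 5, alpha = 0.05,
                            nmr_total = 1000, nmr_min_cv = 0.1,
                            he = list(), seed = 1L) {
  cfg <- list(synthetic = synthetic, counts_path = counts_path,
              nmr_path = nmr_path, clinical_path = clinical_path,
              out_dir = out_dir, rarefy_depth = rarefy_depth,
              filter_threshold = filter_threshold,
              corr_threshold = corr_threshold, resolution = resolution,
              n_restarts = n_restarts, keystone_k = keystone_k,
              alpha = alpha, nmr_total = nmr_total, nmr_min_cv = nmr_min_cv,
              he = he, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "fmn_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$synthetic)) {
    paths <- c(cfg$counts_path, cfg$nmr_path, cfg$clinical_path)
    if (length(paths) < 3) {
      abort("config error: provide either `synthetic` or all three input paths")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(sprintf("config error: missing input path(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  if (cfg$corr_threshold <= 0 || cfg$corr_threshold >= 1) {
    abort("config error: corr_threshold must lie in (0, 1)")
  }
  if (cfg$filter_threshold < 0 || cfg$filter_threshold >= 1) {
    abort("config error: filter_threshold must lie in [0, 1)")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("config error: alpha must lie in (0, 1)")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()] (a `synthetic`
#'   mapping is passed to [cohort_spec()]).
#' @return An `fmn_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(cohort_spec, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full integrated pipeline
#'
#' Executes, per cohort arm (cases and controls): depth normalization,
#' relative abundance, mean-abundance filtering, alpha diversity, Yue &
#' Clayton and Bray-Curtis distance matrices with PCoA and within-group
#' means, NMR bucket normalization (total integral then PQN), the merged
#' functional metagenomic network with FMC detection and descriptor
#' summary, feature-clinical cross-correlation with FDR stars, and the
#' consensus HE risk report. All outputs are written under
#' `config$out_dir` together with a manifest recording seeds, settings
#' and a config hash; reruns with the same config are byte-identical.
#'
#' @param config An `fmn_config`.
#' @return Invisibly, a list with the in-memory results (`diversity`,
#'   `networks`, `summaries`, `crosscorr`, `risk_report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fmn_config"))
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  inputs <- stage("load_inputs", {
    if (!is.null(config$synthetic)) {
      coh <- generate_cohort(config$synthetic)
      list(counts = coh$counts, nmr = coh$nmr, clinical = coh$clinical)
    } else {
      list(
        counts = read_abundance_table(config$counts_path),
        nmr = read_abundance_table(config$nmr_path, kind = "relative"),
        clinical = suppressMessages(readr::read_tsv(config$clinical_path,
                                                    comment = "#",
                                                    show_col_types = FALSE))
      )
    }
  })
  groups <- inputs$clinical[c("sample_id", "group")]

  rel <- stage("abundance", {
    rar <- rarefy_counts(inputs$counts, depth = config$rarefy_depth,
                         seed = config$seed)
    write_abundance_table(rar, out("counts_rarefied.tsv"))
    to_relative(rar)
  })
  filtered <- stage("filter", {
    f <- filter_by_mean_abundance(rel, config$filter_threshold)
    write_abundance_table(f, out("relative_filtered.tsv"))
    f
  })

  diversity <- stage("diversity", {
    a <- alpha_diversity(rel)
    readr::write_tsv(a, out("alpha_diversity.tsv"))
    dists <- list(
      yue_clayton = beta_dissimilarity(rel, "yue_clayton"),
      bray_curtis = beta_dissimilarity(rel, "bray_curtis")
    )
    for (mname in names(dists)) {
      readr::write_tsv(as_tibble(as.matrix(dists[[mname]]), rownames = "sample_id"),
                       out(sprintf("dist_%s.tsv", mname)))
    }
    pc <- pcoa_ordination(dists$yue_clayton, k = 2)
    pc_path <- out("pcoa_yue_clayton.tsv")
    writeLines(sprintf("#eigenvalues=%s",
                       paste(format(pc$eigenvalues, digits = 10), collapse = ",")),
               pc_path)
    suppressMessages(readr::write_tsv(pc$coordinates, pc_path, append = TRUE,
                                      col_names = TRUE))
    wg <- within_group_mean_distance(dists$bray_curtis, groups)
    readr::write_tsv(wg, out("within_group_bray_curtis.tsv"))
    list(alpha = a, dists = dists, pcoa = pc, within_group = wg)
  })

  nmr_norm <- stage("nmr", {
    m <- total_integral_normalize(inputs$nmr, total = config$nmr_total)
    m <- pqn_normalize(m)
    readr::write_tsv(m, out("nmr_normalized.tsv"))
    select_informative_buckets(m, min_cv = config$nmr_min_cv)
  })

  # correlations are computed per cohort arm, never pooled
  arms <- split(groups$sample_id, groups$group)
  per_arm <- stage("network", {
    lapply(setNames(names(arms), names(arms)), function(arm) {
      ids <- arms[[arm]]
      taxa_arm <- filtered[filtered$sample_id %in% ids, ]
      nmr_arm <- nmr_norm[nmr_norm$sample_id %in% ids, ]
      merged <- merge_features(taxa_arm, nmr_arm)
      corr <- pearson_matrix(merged)
      net <- build_network(corr, merged, threshold = config$corr_threshold)
      part <- detect_fmcs(net, resolution = config$resolution,
                          seed = config$seed, n_restarts = config$n_restarts)
      net <- set_communities(net, part)
      summ <- network_summary(net, part, keystone_k = config$keystone_k)
      export_network(net, out(sprintf("network_%s.graphml", arm)), "graphml")
      export_network(net, out(sprintf("network_%s_edges.tsv", arm)), "edge_tsv")
      write_network_summary(summ, out(sprintf("summary_%s.json", arm)),
                            out(sprintf("summary_%s.tsv", arm)))
      list(network = net, partition = part, summary = summ)
    })
  })
  nets <- lapply(per_arm, `[[`, "network")
  summaries <- lapply(per_arm, `[[`, "summary")

  crosscorr <- stage("crosscorr", {
    case_ids <- groups$sample_id[groups$group == "case"]
    if (length(case_ids) < 3) case_ids <- groups$sample_id
    merged_all <- merge_features(filtered[filtered$sample_id %in% case_ids, ],
                                 nmr_norm[nmr_norm$sample_id %in% case_ids, ])
    cc <- crosscorrelate(merged_all,
                         inputs$clinical[setdiff(names(inputs$clinical), c("group", "he"))],
                         alpha = config$alpha)
    readr::write_tsv(as_tibble(cc), out("crosscorrelation.tsv"))
    cc
  })

  risk <- stage("he_risk", {
    merged_all <- merge_features(filtered, nmr_norm)
    he_args <- c(list(features = standardize_features(merged_all),
                      labels = inputs$clinical[c("sample_id", "he")],
                      seed = config$seed), config$he)
    rep <- do.call(fit_he_consensus, he_args)
    readr::write_tsv(as_tibble(rep), out("he_risk_report.tsv"))
    readr::write_tsv(select_he_features(rep), out("he_risk_selected.tsv"))
    rep
  })

  manifest <- stage("manifest", {
    cfg_plain <- unclass(config)
    cfg_plain$synthetic <- if (!is.null(config$synthetic)) {
      unclass(config$synthetic)
    } else NULL
    cfg_path <- out("config.yaml")
    yaml::write_yaml(cfg_plain, cfg_path)
    man <- list(
      package = "fmnet",
      version = as.character(utils::packageVersion("fmnet")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(cfg_path)),
      settings = cfg_plain[setdiff(names(cfg_plain), "synthetic")],
      outputs = sort(setdiff(list.files(config$out_dir), "manifest.json"))
    )
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    man
  })

  invisible(list(diversity = diversity, networks = nets,
                 summaries = summaries, crosscorr = crosscorr,
                 risk_report = risk, manifest = manifest,
                 filtered = filtered, nmr = nmr_norm))
}
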