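# Network export / import: GraphML (via igraph), GEXF (hand-written over
# xml2; igraph has no GEXF writer) and a plain edge-TSV. Each writer has a
# matching reader and the pair round-trips losslessly.

#' Export a network to GraphML, GEXF or edge TSV
#'
#' Nodes carry `kind`, `mean_rel_abund`, `degree`, `betweenness` and
#' `community`; edges carry `r`, `sign` and `cooccurrence`; the
#' correlation threshold travels with the file. The `edge_tsv` format
#' writes one row per edge with the signed `r` and a companion
#' `<path>.nodes.tsv` holding the node table (isolated nodes would
#' otherwise be lost).
#'
#' @param net An `fmn_network` (apply [set_communities()] first if FMC
#'   membership should be included).
#' @param path Output file path.
#' @param format `"graphml"`, `"gexf"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
export_network <- function(net, path, format = c("graphml", "gexf", "edge_tsv")) {
  stopifnot(inherits(net, "fmn_network"))
  format <- match.arg(format)
  nodes <- net$nodes |>
    mutate(community = ifelse(is.na(.data$community), -1L, .data$community),
           mean_rel_abund = ifelse(is.na(.data$mean_rel_abund), -1,
                                   .data$mean_rel_abund))
  switch(format,
    graphml = {
      g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                         vertices = nodes)
      g <- igraph::set_graph_attr(g, "threshold", net$threshold)
      igraph::write_graph(g, path, format = "graphml")
    },
    gexf = write_gexf(nodes, net$edges, net$threshold, path),
    edge_tsv = {
      readr::write_tsv(net$edges, path)
      readr::write_tsv(bind_cols(nodes, tibble(threshold = net$threshold)),
                       paste0(path, ".nodes.tsv"))
    }
  )
  invisible(path)
}

#' Read a network written by [export_network()]
#' @param path File path.
#' @param format Format the file was written in.
#' @return An `fmn_network`.
#' @export
read_network <- function(path, format = c("graphml", "gexf", "edge_tsv")) {
  format <- match.arg(format)
  parts <- switch(format,
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      nodes <- tibble(
        feature = igraph::V(g)$name,
        kind = igraph::V(g)$kind,
        mean_rel_abund = igraph::V(g)$mean_rel_abund,
        degree = as.integer(igraph::V(g)$degree),
        betweenness = igraph::V(g)$betweenness,
        community = as.integer(igraph::V(g)$community)
      )
      ed <- igraph::as_data_frame(g, what = "edges")
      edges <- tibble(from = ed$from, to = ed$to, r = ed$r, sign = ed$sign,
                      cooccurrence = as.integer(ed$cooccurrence))
      list(nodes = nodes, edges = edges,
           threshold = igraph::graph_attr(g, "threshold"))
    },
    gexf = read_gexf(path),
    edge_tsv = {
      edges <- readr::read_tsv(path, show_col_types = FALSE)
      ntab <- readr::read_tsv(paste0(path, ".nodes.tsv"), show_col_types = FALSE)
      list(nodes = ntab |> select(-"threshold") |>
             mutate(degree = as.integer(.data$degree),
                    community = as.integer(.data$community)),
           edges = edges |> mutate(cooccurrence = as.integer(.data$cooccurrence)),
           threshold = ntab$threshold[1])
    }
  )
  nodes <- parts$nodes |>
    mutate(community = ifelse(.data$community < 0, NA_integer_, .data$community),
           mean_rel_abund = ifelse(.data$mean_rel_abund < 0, NA_real_,
                                   .data$mean_rel_abund))
  if (nrow(parts$edges) == 0) {
    parts$edges <- tibble(from = character(), to = character(), r = numeric(),
                          sign = character(), cooccurrence = integer())
  }
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(parts$edges),
                 threshold = parts$threshold),
            class = "fmn_network")
}

num_fmt <- function(x) sprintf("%.17g", x)

write_gexf <- function(nodes, edges, threshold, path) {
  doc <- xml2::xml_new_root("gexf", xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  meta <- xml2::xml_add_child(doc, "meta")
  xml2::xml_add_child(meta, "description", sprintf("threshold=%s", num_fmt(threshold)))
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  natts <- xml2::xml_add_child(graph, "attributes", class = "node")
  node_attrs <- c(kind = "string", mean_rel_abund = "double",
                  degree = "integer", betweenness = "double",
                  community = "integer")
  for (i in seq_along(node_attrs)) {
    xml2::xml_add_child(natts, "attribute", id = names(node_attrs)[i],
                        title = names(node_attrs)[i], type = node_attrs[[i]])
  }
  eatts <- xml2::xml_add_child(graph, "attributes", class = "edge")
  edge_attrs <- c(r = "double", sign = "string", cooccurrence = "integer")
  for (i in seq_along(edge_attrs)) {
    xml2::xml_add_child(eatts, "attribute", id = names(edge_attrs)[i],
                        title = names(edge_attrs)[i], type = edge_attrs[[i]])
  }
  nl <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nl, "node", id = nodes$feature[i],
                              label = nodes$feature[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    vals <- c(kind = nodes$kind[i],
              mean_rel_abund = num_fmt(nodes$mean_rel_abund[i]),
              degree = as.character(nodes$degree[i]),
              betweenness = num_fmt(nodes$betweenness[i]),
              community = as.character(nodes$community[i]))
    for (a in names(vals)) {
      xml2::xml_add_child(av, "attvalue", `for` = a, value = vals[[a]])
    }
  }
  el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(el, "edge", id = as.character(i - 1),
                              source = edges$from[i], target = edges$to[i],
                              weight = num_fmt(abs(edges$r[i])))
    av <- xml2::xml_add_child(ed, "attvalues")
    vals <- c(r = num_fmt(edges$r[i]), sign = edges$sign[i],
              cooccurrence = as.character(edges$cooccurrence[i]))
    for (a in names(vals)) {
      xml2::xml_add_child(av, "attvalue", `for` = a, value = vals[[a]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  desc <- xml2::xml_text(xml2::xml_find_first(doc, ".//meta/description"))
  threshold <- as.numeric(sub("^threshold=", "", desc))
  attvals <- function(node) {
    av <- xml2::xml_find_all(node, "./attvalues/attvalue")
    setNames(xml2::xml_attr(av, "value"), xml2::xml_attr(av, "for"))
  }
  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  nodes <- bind_rows(lapply(node_els, function(nd) {
    v <- attvals(nd)
    tibble(feature = xml2::xml_attr(nd, "id"), kind = v[["kind"]],
           mean_rel_abund = as.numeric(v[["mean_rel_abund"]]),
           degree = as.integer(v[["degree"]]),
           betweenness = as.numeric(v[["betweenness"]]),
           community = as.integer(v[["community"]]))
  }))
  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- bind_rows(lapply(edge_els, function(ed) {
    v <- attvals(ed)
    tibble(from = xml2::xml_attr(ed, "source"),
           to = xml2::xml_attr(ed, "target"),
           r = as.numeric(v[["r"]]), sign = v[["sign"]],
           cooccurrence = as.integer(v[["cooccurrence"]]))
  }))
  list(nodes = nodes, edges = edges, threshold = threshold)
}

#' Write a network summary as JSON and a table-style TSV
#' @param summary An `fmn_summary`.
#' @param path_json,path_tsv Output paths (either may be `NULL`).
#' @return Invisibly, the summary.
#' @export
write_network_summary <- function(summary, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(summary, "fmn_summary"))
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(stats = summary$stats, keystones = summary$keystones,
           keystones_by_kind = summary$keystones_by_kind),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  if (!is.null(path_tsv)) {
    s <- summary$stats
    ks <- summary$keystones
    rows <- tibble(
      parameter = c("Nodes", "Edges", "Synergistic interactions (%)",
                    "Competitive interactions (%)", "Syn/Com ratio",
                    "Density", "Modularity",
                    "Keystone features (BC, FMC, Rel.abund.%)"),
      value = c(
        as.character(s$n_nodes), as.character(s$n_edges),
        sprintf("%d (%s)", s$n_synergistic, format(s$pct_synergistic)),
        sprintf("%d (%s)", s$n_competitive, format(s$pct_competitive)),
        format(s$syn_com_ratio), format(s$density), format(s$modularity),
        paste(sprintf("%s (%.1f, %s, %s)", ks$feature, ks$betweenness,
                      ifelse(is.na(ks$community), "-", as.character(ks$community)),
                      ifelse(is.na(ks$mean_rel_abund), "-",
                             sprintf("%.2f", 100 * ks$mean_rel_abund))),
              collapse = "; ")
      )
    )
    readr::write_tsv(rows, path_tsv)
  }
  invisible(summary)
}
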