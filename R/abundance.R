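#' Read a sample-by-taxon abundance table
#'
#' Reads a delimited (TSV/CSV, inferred from the extension or the first
#' line) abundance table into the tidy layout used throughout the package:
#' one `sample_id` column followed by one numeric column per taxon.
#' `#`-prefixed header comments (e.g. the `#seed=` line written by
#' [write_cohort()]) are skipped.
#'
#' @param path File path.
#' @param orientation `"samples_in_rows"` (default) or `"taxa_in_rows"`;
#'   the latter transposes on read.
#' @param kind `"auto"` (default: all-integer values are counts, otherwise
#'   relative), `"counts"` or `"relative"`.
#' @return A tibble with attribute `kind` set to `"counts"` or `"relative"`.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows", "taxa_in_rows"),
                                 kind = c("auto", "counts", "relative")) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- suppressMessages(readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    name_repair = "minimal"
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("parse error in '%s' at line %d: %s", path,
                  prob$row[1] + 1L, prob$expected[1]))
  }
  names(raw)[1] <- "id"
  if (anyDuplicated(names(raw)[-1])) abort("duplicate column ids")
  if (anyDuplicated(raw$id)) abort("duplicate row ids")
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) abort("non-numeric entries in abundance table")
  rownames(m) <- as.character(raw$id)
  if (orientation == "taxa_in_rows") m <- t(m)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative abundance at sample '%s', taxon '%s'",
                  rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  }
  tbl <- matrix_to_tbl(m)
  if (kind == "auto") {
    kind <- if (all(m == round(m))) "counts" else "relative"
  }
  attr(tbl, "kind") <- kind
  tbl
}

#' Rarefy count rows to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`,
#' mirroring the normalization of all libraries to the read count of the
#' least rich sample (3101 reads in the motivating study). Integer counts
#' are preserved, which keeps richness and Shannon estimates meaningful.
#'
#' @param table Count tibble (`sample_id` + taxon columns).
#' @param depth Target depth; defaults to the minimum sample total.
#' @param seed Seed for the subsampling draw.
#' @return Rarefied count tibble; every row sums to `depth`.
#' @export
rarefy_counts <- function(table, depth = NULL, seed = 1L) {
  m <- feature_matrix(table)
  if (any(m != round(m))) abort("rarefy_counts needs integer counts")
  totals <- rowSums(m)
  depth <- depth %||% min(totals)
  shallow <- rownames(m)[totals < depth]
  if (length(shallow)) {
    abort(sprintf("sample(s) shallower than depth %d: %s", as.integer(depth),
                  paste(shallow, collapse = ", ")))
  }
  out <- with_seed(seed, vegan::rrarefy(m, depth))
  res <- matrix_to_tbl(out)
  attr(res, "kind") <- "counts"
  res
}

#' Convert counts to relative abundances
#'
#' Divides each row by its total. Idempotent on relative input.
#'
#' @param table Abundance tibble.
#' @return Relative-abundance tibble (rows sum to 1).
#' @export
to_relative <- function(table) {
  m <- feature_matrix(table)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("all-zero row(s): %s",
                  paste(rownames(m)[totals <= 0], collapse = ", ")))
  }
  res <- matrix_to_tbl(m / totals)
  attr(res, "kind") <- "relative"
  res
}

#' Filter taxa by mean relative abundance
#'
#' Keeps exactly the taxa whose across-sample mean relative abundance is
#' greater than or equal to `threshold` (inclusive, matching the study's
#' ">= 0.5%" rule). Column order is preserved.
#'
#' @param table Relative-abundance tibble.
#' @param threshold Mean-abundance threshold as a fraction (default 0.005).
#' @return Filtered tibble; a warning is issued if no taxon survives.
#' @export
filter_by_mean_abundance <- function(table, threshold = 0.005) {
  m <- feature_matrix(table)
  keep <- colMeans(m) >= threshold
  if (!any(keep)) warn("no taxa pass the mean-abundance filter")
  res <- table[c(TRUE, keep)]
  attr(res, "kind") <- attr(table, "kind")
  res
}

#' Write an abundance (or any sample-by-feature) tibble as TSV
#' @param table Tibble with a `sample_id` first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
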