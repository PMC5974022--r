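# Internal helpers shared across modules.

# Extract the numeric feature matrix from a tibble whose first column is the
# sample identifier. Returns a matrix with sample ids as rownames.
feature_matrix <- function(tbl, id_col = "sample_id") {
  stopifnot(is.data.frame(tbl))
  if (!id_col %in% names(tbl)) {
    abort(sprintf("column '%s' is required", id_col))
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) abort("duplicate sample ids")
  num <- tbl[setdiff(names(tbl), id_col)]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric feature columns: %s", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  m
}

# Rebuild a sample_id-first tibble from a numeric matrix.
matrix_to_tbl <- function(m, id_col = "sample_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

#' Undirected graph density
#'
#' Fraction of realized edges in a simple undirected graph,
#' `2E / (N (N - 1))`. Used for the network descriptor tables.
#'
#' @param n_nodes Number of nodes (N >= 2).
#' @param n_edges Number of edges.
#' @return Density in `[0, 1]`.
#' @examples
#' graph_density(63, 263)
#' @export
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) abort("density needs at least 2 nodes")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

# Seed helper: derive independent child seeds from one master seed so that
# adding an output stream never perturbs existing ones. Keeps results < 2^31.
derive_seeds <- function(seed, labels) {
  stopifnot(length(seed) == 1, is.finite(seed))
  base <- as.double(seed) %% 2147483647
  offs <- vapply(labels, function(l) {
    sum(utf8ToInt(l) * seq_along(utf8ToInt(l))) %% 99991
  }, double(1))
  setNames(as.integer((base * 31 + offs * 1009 + 17) %% 2147483629) + 1L, labels)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
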