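#' Read a connectivity matrix as an undirected graph
#'
#' Reads a square numeric matrix (CSV, TSV or whitespace-separated, with or
#' without header labels), symmetrizes it by logical OR, binarizes entries at
#' a threshold, drops the diagonal, and returns an undirected simple
#' [igraph][igraph::igraph-package] graph.  This is how weighted or directed
#' anatomical connection matrices (e.g. cortico-cortical projection tables
#' with ordinal strengths 0--3) are reduced to the presence/absence graphs the
#' pipeline analyses: relative weighting is discarded.
#'
#' @param path Path to the matrix file.
#' @param threshold Non-negative numeric; an edge is created where either of
#'   the two symmetric entries exceeds `threshold`. Default 0 (any positive
#'   weight is a connection).
#' @return An undirected simple `igraph` graph with character vertex names.
#'   Labels come from the header row/column when present, otherwise
#'   `v0 .. v(N-1)`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines("0,1,1\n1,0,1\n1,1,0", tf)
#' g <- read_adjacency(tf)
#' igraph::vcount(g); igraph::ecount(g)
#' @export
read_adjacency <- function(path, threshold = 0) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) abort("empty file", class = "hierscale_io_error")
  sep <- if (grepl(",", raw[[1]])) "," else ""
  tok <- lapply(raw, function(l) {
    if (sep == ",") trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    else strsplit(trimws(l), "\\s+")[[1]]
  })
  first_num <- suppressWarnings(as.numeric(tok[[1]]))
  has_header <- anyNA(first_num)
  labels <- NULL
  if (has_header) {
    labels <- tok[[1]]
    tok <- tok[-1]
    # header may or may not include a corner cell for the row-label column
    if (length(labels) == length(tok[[1]])) labels <- labels[-1]
    tok <- lapply(tok, function(x) x[-1])
  }
  n <- length(tok)
  rows <- lapply(tok, function(x) suppressWarnings(as.numeric(x)))
  if (any(vapply(rows, anyNA, logical(1)))) {
    abort("non-numeric cells in matrix body", class = "hierscale_io_error")
  }
  if (any(lengths(rows) != n)) {
    abort(
      sprintf("non-square matrix: %d rows but row lengths %s", n,
              paste(unique(lengths(rows)), collapse = "/")),
      class = "hierscale_io_error"
    )
  }
  m <- do.call(rbind, rows)
  if (is.null(labels)) labels <- paste0("v", seq_len(n) - 1L)
  adj <- (m > threshold) | (t(m) > threshold)   # OR-symmetrize, then binarize
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- labels
  g
}

#' Read a two-column edge list as an undirected graph
#'
#' Lines hold two whitespace- or comma-separated node labels; `#` comment
#' lines are ignored.  Duplicate and reversed pairs collapse to a single
#' undirected edge; self-loops are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph.
#' @export
read_edgelist <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L) abort("no edges", class = "hierscale_io_error")
  tok <- lapply(raw, function(l) {
    if (grepl(",", l)) trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    else strsplit(l, "\\s+")[[1]]
  })
  bad <- which(lengths(tok) != 2L)
  if (length(bad)) {
    abort(sprintf("line %d has %d tokens (expected 2)", bad[[1]],
                  lengths(tok)[bad[[1]]]),
          class = "hierscale_io_error")
  }
  el <- do.call(rbind, tok)
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s)", sum(loops)))
    el <- el[!loops, , drop = FALSE]
  }
  if (nrow(el) == 0L) abort("no edges", class = "hierscale_io_error")
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Induced subgraph on a set of node labels
#'
#' @param g An igraph graph with vertex names.
#' @param nodes Character vector of labels, a subset of `V(g)$name`.
#' @return The induced subgraph; labels preserved.
#' @export
induced_subgraph_labels <- function(g, nodes) {
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) {
    abort(paste0("unknown label(s): ", paste(missing, collapse = ", ")),
          class = "hierscale_io_error")
  }
  igraph::induced_subgraph(g, vids = nodes)
}

#' Write a graph as a dense 0/1 adjacency matrix with labels
#'
#' @param g An igraph graph.
#' @param path Output file path; comma-separated with a header row and a
#'   row-label column, readable back with [read_adjacency()].
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(g, path) {
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  labs <- igraph::V(g)$name
  lines <- c(
    paste(c("node", labs), collapse = ","),
    vapply(seq_len(nrow(a)), function(i) {
      paste(c(labs[[i]], a[i, ]), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a graph as a two-column edge list
#'
#' @param g An igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

# internal: validate an undirected simple named graph, adding names if absent
check_graph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (!igraph::is_simple(g)) g <- igraph::simplify(g)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)) - 1L)
  }
  g
}
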