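#' Common neighbors and local-community links per edge
#'
#' For every edge `{x, y}`: `CN` is the number of common neighbors of the
#' endpoints (the size of the local community around the edge, endpoints
#' excluded) and `LCL` the number of graph edges with both ends among those
#' common neighbors (internal links of the local community).  `LCL` is
#' bounded above by `CN(CN-1)/2`.
#'
#' @param g An igraph graph with at least one edge.
#' @return A tibble `(u, v, CN, LCL)`, one row per edge.
#' @examples
#' edge_cn_lcl(igraph::make_full_graph(4))
#' @export
edge_cn_lcl <- function(g) {
  g <- check_graph(g)
  if (igraph::ecount(g) == 0L) abort("graph has no edges",
                                     class = "hierscale_error")
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  el <- igraph::as_edgelist(g, names = FALSE)
  labs <- igraph::V(g)$name
  cn <- integer(nrow(el)); lcl <- integer(nrow(el))
  for (e in seq_len(nrow(el))) {
    common <- which(a[el[e, 1], ] & a[el[e, 2], ])
    cn[[e]] <- length(common)
    lcl[[e]] <- if (length(common) > 1L)
      sum(a[common, common]) / 2L else 0L
  }
  tibble(u = labs[el[, 1]], v = labs[el[, 2]], CN = cn, LCL = as.integer(lcl))
}

#' Local-community-paradigm summary of a graph
#'
#' Computes the per-edge `(CN, LCL)` decomposition and the LCP correlation:
#' the Pearson correlation of `CN` and `LCL` over edges with `CN > 1`.
#' Values near 1 indicate a self-organized, community-rich topology.  With
#' fewer than 2 qualifying edges, or zero variance in either coordinate, the
#' correlation is reported as 0 with `degenerate = TRUE`.
#'
#' @param g An igraph graph with at least one edge.
#' @return An `lcp_summary`: list with `records` (tibble from
#'   [edge_cn_lcl()]), `lcp_corr`, `degenerate`, `n_used` (edges with
#'   `CN > 1`) and `cn_max`.
#' @export
lcp_summary <- function(g) {
  rec <- edge_cn_lcl(g)
  used <- rec[rec$CN > 1, ]
  degen <- nrow(used) < 2L || var(used$CN) == 0 || var(used$LCL) == 0
  structure(
    list(records = rec,
         lcp_corr = if (degen) 0 else cor(used$CN, used$LCL),
         degenerate = degen,
         n_used = nrow(used),
         cn_max = max(rec$CN)),
    class = "lcp_summary")
}

#' @export
print.lcp_summary <- function(x, ...) {
  cat(sprintf(
    "<lcp_summary> LCP-corr = %.4f%s over %d edges with CN > 1 (max CN %d)\n",
    x$lcp_corr, if (x$degenerate) " (degenerate)" else "", x$n_used,
    x$cn_max))
  invisible(x)
}

#' @export
tidy.lcp_summary <- function(x, ...) x$records

#' @export
glance.lcp_summary <- function(x, ...) {
  tibble(lcp_corr = x$lcp_corr, degenerate = x$degenerate,
         n_used = x$n_used, n_edges = nrow(x$records), cn_max = x$cn_max)
}

#' Level-wise LCP correlations of a module tree
#'
#' Runs [lcp_summary()] on every module at level `L` and averages the
#' LCP correlations over the non-degenerate modules (degenerate / zero
#' entries are excluded from the mean, with the excluded count reported, and
#' the standard error over included modules given for error bars).
#'
#' @param tree A `module_tree`.
#' @param L Level (`1 <= L <= tree_depth(tree)`).
#' @return A list with `per_module` (tibble `module, lcp_corr, degenerate,
#'   n_used`), `mean` (`NA` when every module is degenerate), `se`,
#'   `n_included`, `n_excluded`.
#' @export
level_lcp <- function(tree, L) {
  mods <- modules_at_level(tree, L)
  per <- bind_rows(lapply(names(mods), function(nm) {
    s <- tryCatch(lcp_summary(mods[[nm]]), error = function(e) NULL)
    if (is.null(s)) {
      return(tibble(module = nm, lcp_corr = 0, degenerate = TRUE,
                    n_used = 0L))
    }
    tibble(module = nm, lcp_corr = s$lcp_corr, degenerate = s$degenerate,
           n_used = s$n_used)
  }))
  inc <- per[!per$degenerate & per$lcp_corr != 0, ]
  list(
    per_module = per,
    mean = if (nrow(inc)) mean(inc$lcp_corr) else NA_real_,
    se = if (nrow(inc) > 1) sd(inc$lcp_corr) / sqrt(nrow(inc)) else 0,
    n_included = nrow(inc),
    n_excluded = nrow(per) - nrow(inc))
}
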