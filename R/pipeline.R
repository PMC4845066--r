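#' Run the full hierarchical-topology pipeline
#'
#' One call chains the whole analysis: read/validate the graph, recursively
#' decompose it into a module tree, compute node metrics and
#' degree-conditioned curves for the network and every module, run the
#' power-law existence tests, collapse the curve families with one-parameter
#' scaling, fit the level-wise fractal dimensions, and compute LCP
#' statistics whole-network and per level.
#'
#' @param input An igraph graph, or a file path (read with
#'   [read_adjacency()] or [read_edgelist()] per `format`).
#' @param format `"adj"` or `"edgelist"`, used when `input` is a path.
#' @param threshold Binarization threshold for adjacency input.
#' @param min_split_size,max_levels Decomposition controls
#'   (see [decompose_graph()]).
#' @param k_min Low-degree trim for the log-log fits.
#' @param metrics Which degree-conditioned quantities to analyse.
#' @param n_sims Bootstrap replicates for the power-law tests (publication-strength
#'   default 2500; set lower for quick runs). `0` skips the bootstrap.
#' @param seed Integer seed for all stochastic stages.
#' @param stages Character subset of
#'   `c("decompose", "metrics", "powerlaw", "scaling", "fractal", "lcp")`.
#' @return A `pipeline_result` list with elements `graph`, `tree`,
#'   `node_metrics`, `curves`, `powerlaw` (Table-style tibble of fits),
#'   `scaling` (named list of `scaling_result`), `fractal`
#'   (`fractal_dims` or `NULL` if underdetermined), `lcp`
#'   (whole-network summary + per-level means), and `config`.
#' @examples
#' res <- run_pipeline(rb_hierarchical(2), n_sims = 0)
#' glance(res$tree)
#' @export
run_pipeline <- function(input,
                         format = c("adj", "edgelist"),
                         threshold = 0,
                         min_split_size = 3,
                         max_levels = Inf,
                         k_min = 1,
                         metrics = c("p", "clustering", "neigh_conn",
                                     "betweenness", "closeness",
                                     "eigenvector"),
                         n_sims = 2500L,
                         seed = 1L,
                         stages = c("decompose", "metrics", "powerlaw",
                                    "scaling", "fractal", "lcp")) {
  format <- match.arg(format)
  stages <- match.arg(stages, several.ok = TRUE)
  g <- if (igraph::is_igraph(input)) check_graph(input)
       else if (format == "adj") read_adjacency(input, threshold)
       else read_edgelist(input)
  set.seed(seed)
  res <- list(graph = g,
              config = list(format = format, threshold = threshold,
                            min_split_size = min_split_size,
                            max_levels = max_levels, k_min = k_min,
                            metrics = metrics, n_sims = n_sims, seed = seed,
                            stages = stages))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "hierscale_pipeline_error")
    })
  }
  if ("decompose" %in% stages) {
    res$tree <- run_stage("decompose",
      decompose_graph(g, max_levels = max_levels,
                      min_split_size = min_split_size))
  }
  if ("metrics" %in% stages) {
    res$node_metrics <- run_stage("metrics", node_metrics(g))
    res$curves <- run_stage("metrics", {
      out <- lapply(metrics, function(m) degree_curve(res$node_metrics, m))
      names(out) <- metrics
      out
    })
  }
  if ("powerlaw" %in% stages && !is.null(res$node_metrics)) {
    res$powerlaw <- run_stage("powerlaw", {
      rows <- lapply(metrics, function(m) {
        vals <- if (m == "p") res$node_metrics$k
                else res$node_metrics[[m]]
        vals <- vals[!is.na(vals) & vals > 0]
        mode <- if (m == "p") "discrete" else "continuous"
        fit <- tryCatch(pl_fit(vals, mode = mode),
                        error = function(e) NULL)
        if (is.null(fit)) {
          return(tibble(quantity = m, mode = mode, n = length(vals),
                        x_min = NA_real_, alpha = NA_real_, ks_D = NA_real_,
                        p_value = NA_real_, n_tail = NA_integer_))
        }
        if (n_sims > 0) fit <- pl_gof(fit, n_sims = n_sims)
        tibble(quantity = m, mode = mode, n = fit$n, x_min = fit$x_min,
               alpha = fit$alpha, ks_D = fit$ks_D, p_value = fit$p_value,
               n_tail = fit$n_tail)
      })
      bind_rows(rows)
    })
  }
  if ("scaling" %in% stages && !is.null(res$tree)) {
    res$scaling <- run_stage("scaling", {
      out <- lapply(metrics, function(m) {
        fam <- curve_family(res$tree, m)
        tryCatch(suppressWarnings(collapse_curves(fam, k_min = k_min)),
                 error = function(e) NULL)
      })
      names(out) <- metrics
      out
    })
  }
  if ("fractal" %in% stages && !is.null(res$tree)) {
    res$fractal <- run_stage("fractal",
      tryCatch(fractal_dimensions(res$tree),
               error = function(e) { inform(conditionMessage(e)); NULL }))
  }
  if ("lcp" %in% stages) {
    res$lcp <- run_stage("lcp", {
      whole <- lcp_summary(g)
      lv <- NULL
      if (!is.null(res$tree) && tree_depth(res$tree) >= 1) {
        lv <- bind_rows(lapply(seq_len(tree_depth(res$tree)), function(L) {
          s <- level_lcp(res$tree, L)
          tibble(level = L, mean_lcp_corr = s$mean, se = s$se,
                 n_included = s$n_included, n_excluded = s$n_excluded)
        }))
      }
      list(whole = whole, levels = lv)
    })
  }
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (!is.null(x$tree)) print(glance(x$tree))
  if (!is.null(x$powerlaw)) { cat("power-law tests:\n"); print(x$powerlaw) }
  if (!is.null(x$fractal)) print(x$fractal)
  if (!is.null(x$lcp)) print(x$lcp$whole)
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Serializes the result as plain-text artifacts: the module tree and
#' configuration as JSON, node metrics, degree curves, per-level aggregates,
#' pooled scaling data and LCP records as TSV.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(res, dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_edgelist(res$graph, file.path(dir, "graph.edgelist"))
  if (!is.null(res$tree)) {
    tr <- as_tibble(res$tree)
    tr$nodes <- vapply(tr$nodes, paste, character(1), collapse = ",")
    jsonlite::write_json(tr, file.path(dir, "module_tree.json"),
                         dataframe = "rows", pretty = TRUE)
    wtsv(tidy(res$tree), "node_levels.tsv")
  }
  if (!is.null(res$node_metrics)) wtsv(res$node_metrics, "node_metrics.tsv")
  if (!is.null(res$curves)) {
    for (m in names(res$curves)) wtsv(res$curves[[m]],
                                      sprintf("curve_%s.tsv", m))
  }
  if (!is.null(res$powerlaw)) wtsv(res$powerlaw, "powerlaw_tests.tsv")
  if (!is.null(res$scaling)) {
    for (m in names(res$scaling)) {
      sc <- res$scaling[[m]]
      if (is.null(sc)) next
      wtsv(sc$pooled, sprintf("scaling_pooled_%s.tsv", m))
      jsonlite::write_json(glance(sc), file.path(
        dir, sprintf("scaling_%s.json", m)), auto_unbox = TRUE, pretty = TRUE)
    }
  }
  if (!is.null(res$fractal)) {
    wtsv(res$fractal$aggregates, "level_aggregates.tsv")
    jsonlite::write_json(tidy(res$fractal), file.path(dir, "fractal.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  if (!is.null(res$lcp)) {
    wtsv(res$lcp$whole$records, "lcp_records.tsv")
    jsonlite::write_json(glance(res$lcp$whole),
                         file.path(dir, "lcp_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(res$lcp$levels)) wtsv(res$lcp$levels, "lcp_levels.tsv")
  }
  invisible(dir)
}
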