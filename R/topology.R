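#' Per-node topological metrics
#'
#' Computes, for every node: degree `k`, local clustering coefficient
#' `clustering` (number of linked neighbor pairs over `k(k-1)/2`; 0 by
#' convention for `k < 2`), neighborhood connectivity `neigh_conn` (mean
#' degree of the node's neighbors; `NA` for isolated nodes), normalized
#' betweenness `betweenness` (pair-dependency sum divided by
#' `(N-1)(N-2)/2` unordered pairs excluding the node), closeness `closeness`
#' (reachable-vertex count divided by the sum of geodesic distances to the
#' reachable vertices; 0 for isolated nodes), and eigenvector centrality
#' `eigenvector` (principal adjacency eigenvector, non-negative, max 1).
#'
#' @param g An igraph graph (undirected, simple; coerced if not).
#' @return A tibble with one row per node and columns
#'   `node, k, clustering, neigh_conn, betweenness, closeness, eigenvector`.
#' @examples
#' node_metrics(igraph::make_ring(5))
#' @export
node_metrics <- function(g) {
  g <- check_graph(g)
  n <- igraph::vcount(g)
  k <- igraph::degree(g)
  clust <- igraph::transitivity(g, type = "local", isolates = "zero")
  clust[k < 2] <- 0
  nc <- igraph::knn(g)$knn          # NaN for isolated nodes
  nc[k == 0] <- NA_real_
  if (n < 3) {
    btw <- rep(0, n)
  } else {
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE) /
      ((n - 1) * (n - 2) / 2)
  }
  d <- igraph::distances(g)
  cls <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else length(di) / sum(di)
  }, numeric(1))
  tibble(
    node = igraph::V(g)$name,
    k = as.integer(k),
    clustering = as.numeric(clust),
    neigh_conn = as.numeric(nc),
    betweenness = as.numeric(btw),
    closeness = cls,
    eigenvector = eigenvector_centrality(g)
  )
}

#' Eigenvector centrality (principal adjacency eigenvector)
#'
#' Scores are entries of the principal eigenvector of the adjacency matrix,
#' taken non-negative and scaled so the maximum is 1.  On a disconnected
#' graph each component's principal eigenvector is computed separately,
#' max-normalized, and scaled by `lambda_c / lambda_max` so the global
#' maximum lies in the spectrally dominant component.
#'
#' @param g An igraph graph.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
eigenvector_centrality <- function(g) {
  g <- check_graph(g)
  n <- igraph::vcount(g)
  out <- setNames(numeric(n), igraph::V(g)$name)
  comp <- igraph::components(g)
  lam <- numeric(comp$no)
  vecs <- vector("list", comp$no)
  for (c_i in seq_len(comp$no)) {
    vids <- which(comp$membership == c_i)
    if (length(vids) == 1L) { lam[c_i] <- 0; vecs[[c_i]] <- 0; next }
    a <- as.matrix(igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, vids), sparse = FALSE))
    e <- eigen(a, symmetric = TRUE)
    lam[c_i] <- e$values[[1]]
    v <- e$vectors[, 1]
    v <- abs(v)                     # Perron vector is sign-definite
    vecs[[c_i]] <- v / max(v)
  }
  lmax <- max(lam)
  for (c_i in seq_len(comp$no)) {
    vids <- which(comp$membership == c_i)
    sc <- if (lmax > 0) lam[c_i] / lmax else 1
    out[vids] <- vecs[[c_i]] * sc
  }
  out
}

#' Degree distribution P(k)
#'
#' @param g An igraph graph.
#' @return A tibble `(k, value, n_nodes)` where `value = n_k / N`; values sum
#'   to 1 over the observed degrees.
#' @export
degree_distribution_curve <- function(g) {
  g <- check_graph(g)
  k <- igraph::degree(g)
  tab <- table(k)
  tibble(
    k = as.integer(names(tab)),
    value = as.numeric(tab) / igraph::vcount(g),
    n_nodes = as.integer(tab)
  )
}

#' Degree-conditioned curve of a node metric
#'
#' Averages a per-node metric over each exact degree class (no log-binning).
#' `metric = "p"` returns the degree distribution itself.  Nodes whose metric
#' is `NA` (isolated nodes for neighborhood connectivity) are excluded.
#'
#' @param g An igraph graph, or a tibble from [node_metrics()].
#' @param metric One of `"p"`, `"clustering"`, `"neigh_conn"`,
#'   `"betweenness"`, `"closeness"`, `"eigenvector"`.
#' @return A tibble `(k, value, n_nodes)` with strictly increasing `k`.
#' @examples
#' degree_curve(igraph::make_full_graph(4), "clustering")
#' @export
degree_curve <- function(g, metric = c("p", "clustering", "neigh_conn",
                                       "betweenness", "closeness",
                                       "eigenvector")) {
  metric <- match.arg(metric)
  if (igraph::is_igraph(g)) {
    if (metric == "p") return(degree_distribution_curve(g))
    nm <- node_metrics(g)
  } else {
    nm <- g
    if (metric == "p") {
      tab <- table(nm$k)
      return(tibble(k = as.integer(names(tab)),
                    value = as.numeric(tab) / nrow(nm),
                    n_nodes = as.integer(tab)))
    }
  }
  nm %>%
    filter(!is.na(.data[[metric]])) %>%
    group_by(k = .data$k) %>%
    summarise(value = mean(.data[[metric]]), n_nodes = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$k)
}

#' Diameter of the largest connected component
#'
#' @param g An igraph graph.
#' @return Integer; maximum eccentricity within the largest component
#'   (ties broken by first component found); 0 for a single node.
#' @export
diameter_lcc <- function(g) {
  g <- check_graph(g)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) == 1L) return(0L)
  as.integer(igraph::diameter(sub, directed = FALSE))
}
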