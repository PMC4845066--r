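# Brute-force oracles, independent of the implementation under test: all
# operate on a plain 0/1 adjacency matrix and use exhaustive enumeration.

# random labelled graph as igraph + adjacency matrix
random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(n) - 1L)
  list(g = g, a = a)
}

# all-pairs shortest-path distances by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# enumerate all simple paths s -> t by DFS; return those of minimum length
oracle_shortest_paths <- function(a, s, t) {
  n <- nrow(a)
  paths <- list()
  walk <- function(path) {
    v <- path[[length(path)]]
    if (v == t) { paths[[length(paths) + 1L]] <<- path; return() }
    for (w in which(a[v, ] > 0)) if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  if (length(paths) == 0L) return(list())
  len <- vapply(paths, length, integer(1))
  paths[len == min(len)]
}

# normalized betweenness by exhaustive shortest-path enumeration
oracle_betweenness <- function(a) {
  n <- nrow(a)
  if (n < 3) return(numeric(n))
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    sp <- oracle_shortest_paths(a, s, t)
    if (length(sp) == 0L) next
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      through <- sum(vapply(sp, function(p) i %in% p[-c(1, length(p))],
                            logical(1)))
      b[i] <- b[i] + through / length(sp)
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# closeness with the reachable-only convention
oracle_closeness <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else length(di) / sum(di)
  }, numeric(1))
}

# local clustering: linked neighbor pairs / k(k-1)/2, zero for k < 2
oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_neigh_conn <- function(a) {
  deg <- rowSums(a)
  vapply(seq_len(nrow(a)), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) == 0L) NA_real_ else mean(deg[nb])
  }, numeric(1))
}

# per-edge common neighbors / local-community links
oracle_cn_lcl <- function(a) {
  n <- nrow(a)
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (a[i, j] == 0) next
    common <- which(a[i, ] > 0 & a[j, ] > 0)
    cn <- length(common)
    lcl <- if (cn > 1) sum(a[common, common]) / 2 else 0
    out <- rbind(out, c(i, j, cn, lcl))
  }
  out
}

# modularity by the direct double sum over all node pairs
oracle_modularity <- function(a, mem) {
  m2 <- sum(a)
  if (m2 == 0) stop("empty graph")
  k <- rowSums(a)
  same <- outer(mem, mem, "==")
  sum((a - outer(k, k) / m2) * same) / m2
}

# best bipartition (and trivial single community) by exhaustive search
oracle_best_bipartition_q <- function(a) {
  n <- nrow(a)
  best <- 0  # single community has Q = 0
  for (mask in 1:(2^(n - 1) - 1)) {
    mem <- as.integer(intToBits(mask))[1:n]
    best <- max(best, oracle_modularity(a, mem))
  }
  best
}

# two triangles joined by one bridge edge, a recurring fixture
two_triangle_bridge <- function() {
  g <- igraph::graph_from_edgelist(rbind(
    c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
    c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
    c("a1", "b1")), directed = FALSE)
  g
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}
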