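#' Newman modularity of a labelled partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j).
#'
#' @param g An igraph graph with at least one edge.
#' @param membership Community assignment: either a named vector (names =
#'   node labels) or a vector aligned with `V(g)`.
#' @return Modularity Q in `[-1, 1)`.
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' g <- igraph::add_edges(g, c(1, 4))
#' modularity_q(g, rep(1:2, each = 3))   # 5/14
#' @export
modularity_q <- function(g, membership) {
  g <- check_graph(g)
  if (igraph::ecount(g) == 0L) {
    abort("modularity undefined on empty graph", class = "hierscale_error")
  }
  if (!is.null(names(membership))) {
    membership <- membership[igraph::V(g)$name]
  }
  stopifnot(length(membership) == igraph::vcount(g), !anyNA(membership))
  igraph::modularity(g, as.integer(factor(membership)))
}

# Kernighan-Lin-style vector fine-tuning of a sign split: repeatedly sweep
# over the nodes, flipping each once in order of best gain in s'Bg s, and
# keep the best configuration seen. Deterministic.
refine_split <- function(Bg, s) {
  n <- length(s)
  best_s <- s
  best_val <- as.numeric(t(s) %*% Bg %*% s)
  repeat {
    s_cur <- best_s
    val_cur <- best_val
    free <- rep(TRUE, n)
    improved <- FALSE
    for (step in seq_len(n)) {
      bs <- as.vector(Bg %*% s_cur)
      gains <- -4 * s_cur * bs + 4 * diag(Bg)
      gains[!free] <- -Inf
      i <- which.max(gains)
      s_cur[i] <- -s_cur[i]
      val_cur <- val_cur + gains[i]
      free[i] <- FALSE
      if (val_cur > best_val + 1e-12) {
        best_val <- val_cur
        best_s <- s_cur
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best_s
}

# Leading-eigenvector recursive bipartitioning (Newman 2006) on one connected
# graph. Works on the generalized modularity matrix restricted to the current
# subgroup; sign ties (entry == 0) go to the positive side; a subgroup is left
# alone when its leading eigenvalue <= eps or the split does not increase Q.
split_group <- function(B, idx, eps) {
  Bg <- B[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)   # generalized modularity matrix
  if (length(idx) == 1L) return(list(idx))
  e <- eigen(Bg, symmetric = TRUE)
  if (e$values[[1]] <= eps) return(list(idx))
  v <- e$vectors[, 1]
  s <- ifelse(v >= 0, 1, -1)
  s <- refine_split(Bg, s)
  dq <- as.numeric(t(s) %*% Bg %*% s)  # proportional to modularity gain
  if (dq <= eps || all(s == s[[1]])) return(list(idx))
  c(split_group(B, idx[s > 0], eps), split_group(B, idx[s < 0], eps))
}

#' Leading-eigenvector modularity partition
#'
#' Newman's spectral community detection: the modularity matrix
#' `B = A - k k' / 2m` is split by the sign pattern of its leading
#' eigenvector, and each part is recursively re-split using the generalized
#' modularity matrix restricted to the subgroup, until the leading eigenvalue
#' is non-positive or a split no longer increases Q.  Disconnected input is
#' first separated into components (each component is its own module
#' candidate).
#'
#' @param g An igraph graph with at least one edge.
#' @param eps Numeric tolerance for the leading eigenvalue / modularity gain
#'   (default 1e-10).
#' @return A list with `membership` (named integer vector, 0-based contiguous
#'   community ids), `q` (modularity of the partition), and `indivisible`
#'   (logical: `TRUE` when the graph was not split).
#' @export
leading_eigen_split <- function(g, eps = 1e-10) {
  g <- check_graph(g)
  if (igraph::ecount(g) == 0L) {
    abort("cannot partition a graph with no edges", class = "hierscale_error")
  }
  n <- igraph::vcount(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  k <- rowSums(a)
  m2 <- sum(k)
  B <- a - outer(k, k) / m2
  comp <- igraph::components(g)
  groups <- list()
  for (c_i in seq_len(comp$no)) {
    idx <- which(comp$membership == c_i)
    groups <- c(groups, split_group(B, idx, eps))
  }
  membership <- integer(n)
  for (i in seq_along(groups)) membership[groups[[i]]] <- i - 1L
  names(membership) <- igraph::V(g)$name
  q <- igraph::modularity(g, membership + 1L)
  list(membership = membership, q = q,
       indivisible = length(groups) == 1L)
}

#' Recursive modular decomposition into a module tree
#'
#' Applies [leading_eigen_split()] to the whole graph (level 0), then
#' re-splits every resulting module on its induced subgraph, and so on.  A
#' module is terminal when it is a triangular motif (3 nodes, 3 edges), has
#' at most `min_split_size` nodes, or the split declares it indivisible.
#' Terminal modules are not carried into deeper levels.  Module order within
#' a level is deterministic (by smallest member label).
#'
#' @param g An igraph graph.
#' @param max_levels Maximum depth of the tree (default `Inf`).
#' @param min_split_size Modules with at most this many nodes are terminal
#'   (default 3).
#' @param eps Tolerance passed to [leading_eigen_split()].
#' @return A `module_tree`: a tibble with columns `id`, `level`, `parent`,
#'   `nodes` (list of label vectors), `n_nodes`, `n_edges`, `terminal`, and
#'   the root graph in attribute `graph`.
#' @examples
#' tr <- decompose_graph(rb_hierarchical(2))
#' tr
#' @export
decompose_graph <- function(g, max_levels = Inf, min_split_size = 3,
                            eps = 1e-10) {
  g <- check_graph(g)
  if (igraph::vcount(g) == 0L) abort("empty graph", class = "hierscale_error")
  rows <- list()
  next_id <- 0L
  add_row <- function(level, parent, nodes, terminal, sub) {
    id <- next_id
    next_id <<- next_id + 1L
    nn <- length(nodes)
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, level = level, parent = parent, nodes = list(nodes),
      n_nodes = nn, n_edges = as.integer(igraph::ecount(sub)),
      terminal = terminal
    )
    id
  }
  is_terminal_motif <- function(sub) {
    igraph::vcount(sub) == 3L && igraph::ecount(sub) == 3L
  }
  # queue of (parent id, node labels) to split
  recurse <- function(nodes, level, parent) {
    sub <- induced_subgraph_labels(g, nodes)
    terminal <- is_terminal_motif(sub) ||
      length(nodes) <= min_split_size ||
      level >= max_levels ||
      igraph::ecount(sub) == 0L
    sp <- NULL
    if (!terminal) {
      sp <- leading_eigen_split(sub, eps)
      terminal <- sp$indivisible
    }
    id <- add_row(level, parent, nodes, terminal, sub)
    if (!terminal) {
      parts <- split(names(sp$membership), sp$membership)
      parts <- parts[order(vapply(parts, min, character(1)))]
      for (p in parts) recurse(sort(p), level + 1L, id)
    }
    id
  }
  recurse(sort(igraph::V(g)$name), 0L, NA_integer_)
  tree <- bind_rows(rows) %>% arrange(.data$level, .data$id)
  structure(tree, class = c("module_tree", class(tree)), graph = g)
}

#' Build a module tree from planted level memberships
#'
#' Constructs a `module_tree` directly from known (e.g. planted) nested
#' memberships instead of running the spectral decomposition — useful for
#' benchmark comparisons against generators with ground truth.
#'
#' @param g The root igraph graph.
#' @param memberships A list of named membership vectors, one per level
#'   (coarsest first); each must be nested within the previous one.
#' @return A `module_tree`.
#' @export
module_tree_from_membership <- function(g, memberships) {
  g <- check_graph(g)
  labs <- sort(igraph::V(g)$name)
  rows <- list()
  next_id <- 0L
  add_row <- function(level, parent, nodes, terminal) {
    id <- next_id
    next_id <<- next_id + 1L
    sub <- induced_subgraph_labels(g, nodes)
    nn <- length(nodes)
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, level = level, parent = parent, nodes = list(nodes),
      n_nodes = nn, n_edges = as.integer(igraph::ecount(sub)),
      terminal = terminal
    )
    id
  }
  recurse <- function(nodes, level, parent) {
    terminal <- level >= length(memberships)
    id <- add_row(level, parent, nodes, terminal)
    if (!terminal) {
      mem <- memberships[[level + 1L]][nodes]
      if (anyNA(mem)) abort("membership does not cover all nodes",
                            class = "hierscale_error")
      parts <- split(nodes, mem)
      parts <- parts[order(vapply(parts, min, character(1)))]
      for (p in parts) recurse(sort(unname(p)), level + 1L, id)
    }
  }
  recurse(labs, 0L, NA_integer_)
  tree <- bind_rows(rows) %>% arrange(.data$level, .data$id)
  structure(tree, class = c("module_tree", class(tree)), graph = g)
}

#' Depth of a module tree
#' @param tree A `module_tree`.
#' @return Integer, the deepest level present (root = level 0).
#' @export
tree_depth <- function(tree) max(tree$level)

#' Module subgraphs at a given level
#'
#' Returns the induced subgraphs of all modules whose level equals `L`.
#' Modules that became terminal at a shallower level are not propagated
#' forward.  Order is deterministic (by smallest member label).
#'
#' @param tree A `module_tree` from [decompose_graph()].
#' @param L Level, `1 <= L <= tree_depth(tree)`.
#' @return A named list of igraph graphs.
#' @export
modules_at_level <- function(tree, L) {
  if (L < 1 || L > tree_depth(tree)) {
    abort(sprintf("level %s out of range [1, %d]", L, tree_depth(tree)),
          class = "hierscale_error")
  }
  g <- attr(tree, "graph")
  rows <- tree[tree$level == L, ]
  rows <- rows[order(vapply(rows$nodes, min, character(1))), ]
  out <- lapply(rows$nodes, function(nd) induced_subgraph_labels(g, nd))
  names(out) <- paste0("L", L, "M", rows$id)
  out
}

#' @export
print.module_tree <- function(x, ...) {
  cat(sprintf(
    "<module_tree> %d modules over levels 0..%d (root: %d nodes, %d edges)\n",
    nrow(x), tree_depth(x), igraph::vcount(attr(x, "graph")),
    igraph::ecount(attr(x, "graph"))))
  NextMethod()
}

#' Tidy a module tree into a per-node level table
#'
#' @param x A `module_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node and one column `level_<L>` per
#'   level holding the module id containing that node (NA once its branch
#'   has terminated).
#' @export
tidy.module_tree <- function(x, ...) {
  g <- attr(x, "graph")
  labs <- igraph::V(g)$name
  out <- tibble(node = labs)
  for (L in seq_len(max(1L, tree_depth(x)))) {
    if (L > tree_depth(x)) break
    col <- rep(NA_integer_, length(labs))
    rows <- x[x$level == L, ]
    for (i in seq_len(nrow(rows))) {
      col[match(rows$nodes[[i]], labs)] <- rows$id[[i]]
    }
    out[[paste0("level_", L)]] <- col
  }
  out
}

#' @export
glance.module_tree <- function(x, ...) {
  tibble(
    depth = tree_depth(x),
    n_modules = sum(x$level > 0),
    n_terminal = sum(x$terminal),
    n_triangle_motifs = sum(x$terminal & x$n_nodes == 3 & x$n_edges == 3)
  )
}
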