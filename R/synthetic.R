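#' Continuous power-law (Pareto) sampler
#'
#' Inverse-CDF sampling: `x = x_min * (1 - u)^(-1/(alpha-1))` with
#' `u ~ U[0, 1)`.
#'
#' @param n Sample size.
#' @param alpha Exponent `> 1`.
#' @param x_min Lower bound `> 0`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`, all `>= x_min`.
#' @export
rpl_continuous <- function(n, alpha, x_min, seed = NULL) {
  stopifnot(alpha > 1, x_min > 0)
  if (!is.null(seed)) set.seed(seed)
  x_min * (1 - runif(n))^(-1 / (alpha - 1))
}

#' Discrete power-law (Hurwitz zeta) sampler
#'
#' Samples from `P(X = x) = x^-alpha / zeta(alpha, x_min)` on integers
#' `x >= x_min` by inverse transform on the cumulative zeta tail
#' probabilities; the CDF table is extended by doubling until it covers the
#' drawn uniforms, with a Hurwitz-zeta bisection fallback for extreme tail
#' draws.
#'
#' @param n Sample size.
#' @param alpha Exponent `> 1`.
#' @param x_min Integer lower bound `>= 1`.
#' @param seed Optional integer seed.
#' @return Integer-valued numeric vector, all `>= x_min`.
#' @export
rpl_discrete <- function(n, alpha, x_min, seed = NULL) {
  stopifnot(alpha > 1, x_min >= 1, x_min == round(x_min))
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  z0 <- hzeta(alpha, x_min)
  len <- 4096L
  repeat {
    vals <- x_min + seq_len(len) - 1
    cdf <- cumsum(vals^(-alpha)) / z0
    if (max(u) <= cdf[[len]] || len >= 2^24) break
    len <- len * 4L
  }
  idx <- findInterval(u, cdf) + 1L
  out <- vals[pmin(idx, len)]
  over <- which(u > cdf[[len]])
  for (i in over) {   # extreme tail: bisect on the zeta survival function
    lo <- vals[[len]]; hi <- lo * 2
    surv <- function(v) hzeta(alpha, v) / z0   # P(X >= v)
    while (surv(hi + 1) > 1 - u[[i]]) { lo <- hi; hi <- hi * 2 }
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (surv(mid + 1) > 1 - u[[i]]) lo <- mid else hi <- mid
    }
    out[[i]] <- hi
  }
  out
}

#' Deterministic Ravasz-Barabasi hierarchical graph
#'
#' Level 1 is a 5-clique with a designated central hub; each further level
#' makes four copies of the current graph and wires every peripheral node of
#' the copies to the central hub of the original.  The result is the classic
#' deterministic hierarchical scale-free network with `N = 5^levels` nodes
#' and clustering curve `C(k) ~ k^-1`, the canonical signature of
#' hierarchical modularity.
#'
#' @param levels Integer in 1..5.
#' @return An igraph graph with `5^levels` nodes; vertex attribute `name` is
#'   `v0..v(N-1)` with `v0` the central hub.
#' @examples
#' g <- rb_hierarchical(2)
#' igraph::degree(g, "v0")   # 20
#' @export
rb_hierarchical <- function(levels) {
  stopifnot(levels >= 1, levels <= 5)
  # node 1 = center, nodes 2:5 = periphery of the base clique
  edges <- utils::combn(1:5, 2)
  el <- t(edges)
  center <- 1L
  periph <- 2:5
  n <- 5L
  if (levels > 1) {
    for (lv in 2:levels) {
      el0 <- el
      periph_new <- integer(0)
      for (cp in 1:4) {
        off <- n * cp
        el <- rbind(el, el0 + off)
        periph_new <- c(periph_new, periph + off)
      }
      el <- rbind(el, cbind(periph_new, center))
      periph <- periph_new
      n <- n * 5L
    }
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n) - 1L)
  g
}

#' Nested stochastic block model with planted hierarchy
#'
#' Nodes are grouped into `branching^depth` leaf blocks of `leaf_size`
#' nodes arranged on a balanced tree.  The probability of an edge between
#' two nodes is `p_levels[j + 1]` where `j` is the tree distance of their
#' lowest common ancestor from the leaf tier (`j = 0`: same leaf block).
#' Strictly decreasing `p_levels` plants a hierarchy of nested modules with
#' geometrically weakening inter-module coupling.
#'
#' @param branching Children per internal tree node (`>= 2`).
#' @param depth Number of nested tiers (`>= 0`).
#' @param leaf_size Nodes per leaf block.
#' @param p_levels Numeric vector of `depth + 1` strictly decreasing edge
#'   probabilities in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with `graph` (igraph) and `membership`: a list of named
#'   block-id vectors, coarsest tier first, suitable for
#'   [module_tree_from_membership()].
#' @export
nested_sbm <- function(branching, depth, leaf_size, p_levels, seed = NULL) {
  stopifnot(branching >= 2 || depth == 0, depth >= 0,
            length(p_levels) == depth + 1,
            all(p_levels > 0), all(p_levels <= 1))
  if (depth > 0 && any(diff(p_levels) >= 0)) {
    abort("p_levels must be strictly decreasing", class = "hierscale_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_leaves <- branching^depth
  n <- n_leaves * leaf_size
  leaf <- rep(seq_len(n_leaves) - 1L, each = leaf_size)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  li <- leaf[pair[, 1]]; lj <- leaf[pair[, 2]]
  # LCA height above the leaf tier = number of base-`branching` digit shifts
  # until the two leaf indices coincide
  height <- integer(nrow(pair))
  if (depth > 0) {
    a <- li; b <- lj
    for (h in seq_len(depth)) {
      diffnow <- a != b
      height[diffnow] <- height[diffnow] + 1L
      a <- a %/% branching; b <- b %/% branching
    }
  }
  p_edge <- p_levels[height + 1L]
  sel <- runif(nrow(pair)) < p_edge
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%04d", seq_len(n) - 1L)
  if (any(sel)) {
    g <- igraph::add_edges(g, rbind(pair[sel, 1], pair[sel, 2]))
  }
  membership <- list()
  if (depth > 0) {
    labs <- igraph::V(g)$name
    for (tier in seq_len(depth)) {
      block <- leaf %/% branching^(depth - tier)
      membership[[tier]] <- setNames(block, labs)
    }
  }
  list(graph = g, membership = membership)
}

#' Erdos-Renyi random graph G(n, p)
#'
#' Null model without local-community structure: every unordered pair is an
#' edge independently with probability `p`.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An igraph graph with names `v0..v(n-1)`.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n) - 1L)
  g
}
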