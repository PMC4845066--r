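# Engineered three-tier graph with exact level aggregates:
# tier-3 modules are triangles (N=3, r=1), tier-2 blocks are 4 triangles with
# one hub triangle fully wired to the others (N=12, r=2), tier-1 components
# are 4 blocks bridged through hub nodes (N=48, r=4), so N = 3 r^2 at every
# level. Returns the graph plus planted memberships for
# module_tree_from_membership().
exact_fractal_fixture <- function(n_components = 2, prefix = "x") {
  edges <- NULL
  tier1 <- tier2 <- tier3 <- integer(0)
  labs <- character(0)
  nid <- function(comp, blk, tri, v) sprintf("%s_c%d_b%d_t%d_v%d",
                                             prefix, comp, blk, tri, v)
  for (comp in seq_len(n_components)) {
    for (blk in 0:3) {
      for (tri in 0:3) {
        v <- vapply(0:2, function(k) nid(comp, blk, tri, k), character(1))
        labs <- c(labs, v)
        tier1 <- c(tier1, rep(comp, 3))
        tier2 <- c(tier2, rep(comp * 10 + blk, 3))
        tier3 <- c(tier3, rep(comp * 100 + blk * 10 + tri, 3))
        edges <- rbind(edges, cbind(v[c(1, 2, 1)], v[c(2, 3, 3)]))
      }
      # hub triangle (tri 0) fully wired to the three satellite triangles
      for (tri in 1:3) for (i in 0:2) for (j in 0:2) {
        edges <- rbind(edges, cbind(nid(comp, blk, 0, i),
                                    nid(comp, blk, tri, j)))
      }
    }
    # block hubs bridged to block-0 hub: diameter 4 across the component
    for (blk in 1:3) {
      edges <- rbind(edges, cbind(nid(comp, 0, 0, 0), nid(comp, blk, 0, 0)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- function(x) setNames(x, labs)
  list(graph = g,
       membership = list(memb(tier1), memb(tier2), memb(tier3)))
}
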