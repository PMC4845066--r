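#' Per-level module aggregates
#'
#' For every level `L >= 1` of a module tree: `m` (module count), `r` (mean
#' module diameter, largest-component convention), `N` (mean node count),
#' `E` (mean intra-module edge count), and `Gamma` (mean number of root-graph
#' edges crossing a pair of modules, averaged over *all* unordered module
#' pairs at the level, zero-edge pairs included; `NA` when the level has a
#' single module).
#'
#' @param tree A `module_tree`.
#' @param levels Integer vector of levels to aggregate; default all.
#' @return A tibble `(level, m, r, N, E, Gamma)`, one row per level.
#' @export
level_aggregates <- function(tree, levels = seq_len(tree_depth(tree))) {
  if (tree_depth(tree) < 1) abort("tree has no levels below the root",
                                  class = "hierscale_error")
  g <- attr(tree, "graph")
  el <- igraph::as_edgelist(g)
  rows <- lapply(levels, function(L) {
    mods <- modules_at_level(tree, L)
    m <- length(mods)
    diams <- vapply(mods, diameter_lcc, integer(1))
    ncnt <- vapply(mods, igraph::vcount, numeric(1))
    ecnt <- vapply(mods, igraph::ecount, numeric(1))
    gamma <- NA_real_
    if (m >= 2) {
      mem <- setNames(rep(NA_integer_, igraph::vcount(g)), igraph::V(g)$name)
      for (i in seq_along(mods)) mem[igraph::V(mods[[i]])$name] <- i
      mu <- mem[el[, 1]]; mv <- mem[el[, 2]]
      crossing <- sum(!is.na(mu) & !is.na(mv) & mu != mv)
      gamma <- crossing / choose(m, 2)
    }
    tibble(level = L, m = m, r = mean(diams), N = mean(ncnt),
           E = mean(ecnt), Gamma = gamma)
  })
  bind_rows(rows)
}

#' Power-law fit of a level-wise aggregate
#'
#' Least squares of `log10 y` on `log10 r`; the signed slope is the fractal
#' exponent (inter-modular coupling may decrease with diameter, giving a
#' negative slope).  With exactly 2 points the line is exact and the fit is
#' flagged underdetermined.
#'
#' @param r Positive abscissae (mean diameters).
#' @param y Positive ordinates (mean mass / edge counts).
#' @return A list `exponent, stderr, r2, n, underdetermined`.
#' @export
fit_dimension <- function(r, y) {
  keep <- !is.na(r) & !is.na(y)
  r <- r[keep]; y <- y[keep]
  if (length(r) < 2L || length(unique(r)) < 2L) {
    abort("need >= 2 points with distinct r", class = "hierscale_error")
  }
  if (any(r <= 0) || any(y <= 0)) {
    abort("non-positive values in log fit", class = "hierscale_error")
  }
  fit <- lm(log10(y) ~ log10(r))
  s <- suppressWarnings(summary(fit))
  under <- length(r) == 2L
  list(exponent = unname(coef(fit)[[2]]),
       stderr = if (under) 0 else unname(s$coefficients[2, 2]),
       r2 = s$r.squared, n = length(r), underdetermined = under)
}

#' Fractal dimensions of a module tree
#'
#' Fits the three level-wise power laws across decomposition levels:
#' mean module mass `N(r) ~ r^d` (the Hausdorff-type module dimension),
#' mean intra-module edges `E(r) ~ r^f`, and mean inter-modular edges per
#' module pair `Gamma(r) ~ r^g`.  Levels whose mean diameter is 0
#' (single-node modules only) are excluded from the log fits with a
#' reported count; the whole network can optionally enter as a level-0
#' point.
#'
#' @param tree A `module_tree` with at least 2 usable levels.
#' @param include_root Add the whole network as an `L = 0` data point
#'   (default `FALSE`).
#' @return A `fractal_dims` object: list with `d`, `f`, `g` (each a
#'   [fit_dimension()] result), the `aggregates` table, and
#'   `n_levels_dropped`.
#' @examples
#' dims <- fractal_dimensions(decompose_graph(rb_hierarchical(3)))
#' glance(dims)
#' @export
fractal_dimensions <- function(tree, include_root = FALSE) {
  agg <- level_aggregates(tree)
  if (include_root) {
    g <- attr(tree, "graph")
    agg <- bind_rows(
      tibble(level = 0L, m = 1L, r = mean(diameter_lcc(g)),
             N = igraph::vcount(g), E = as.numeric(igraph::ecount(g)),
             Gamma = NA_real_),
      agg)
  }
  usable <- agg[agg$r > 0, ]
  dropped <- nrow(agg) - nrow(usable)
  if (nrow(usable) < 2L) abort("fewer than 2 usable levels",
                               class = "hierscale_error")
  gam <- usable[!is.na(usable$Gamma) & usable$Gamma > 0, ]
  structure(
    list(
      d = fit_dimension(usable$r, usable$N),
      f = fit_dimension(usable$r, usable$E),
      g = if (nrow(gam) >= 2L && length(unique(gam$r)) >= 2L)
        fit_dimension(gam$r, gam$Gamma) else NULL,
      aggregates = agg,
      n_levels_dropped = dropped),
    class = "fractal_dims")
}

#' @export
print.fractal_dims <- function(x, ...) {
  fmt <- function(f) if (is.null(f)) "NA" else sprintf("%.3f", f$exponent)
  cat(sprintf(
    "<fractal_dims> d = %s (mass), f = %s (intra-edges), g = %s (inter-edges), %d levels\n",
    fmt(x$d), fmt(x$f), fmt(x$g), nrow(x$aggregates)))
  invisible(x)
}

#' @export
tidy.fractal_dims <- function(x, ...) {
  rows <- lapply(c(d = "d", f = "f", g = "g"), function(nm) x[[nm]])
  bind_rows(lapply(names(rows), function(nm) {
    f <- rows[[nm]]
    if (is.null(f)) return(tibble(term = nm, estimate = NA_real_,
                                  std.error = NA_real_, r2 = NA_real_))
    tibble(term = nm, estimate = f$exponent, std.error = f$stderr, r2 = f$r2)
  }))
}

#' @export
glance.fractal_dims <- function(x, ...) {
  tibble(
    d = x$d$exponent, f = x$f$exponent,
    g = if (is.null(x$g)) NA_real_ else x$g$exponent,
    n_levels = nrow(x$aggregates), n_levels_dropped = x$n_levels_dropped)
}
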