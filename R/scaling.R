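#' Degree-conditioned curve family across a module tree
#'
#' Computes the degree-conditioned curve of `metric` for the whole network
#' (the `"root"` reference member) and for every module and sub-module at
#' every level of the tree, returned in long form for the one-parameter
#' scaling collapse.
#'
#' @param tree A `module_tree` from [decompose_graph()].
#' @param metric Metric name as in [degree_curve()].
#' @return A `curve_family` tibble with columns
#'   `source, level, k, value, n_nodes`; the root curve has
#'   `source = "root"`, `level = 0`.
#' @export
curve_family <- function(tree, metric = c("p", "clustering", "neigh_conn",
                                          "betweenness", "closeness",
                                          "eigenvector")) {
  metric <- match.arg(metric)
  g <- attr(tree, "graph")
  fam <- list(mutate(degree_curve(g, metric), source = "root", level = 0L))
  depth <- tree_depth(tree)
  if (depth >= 1) {
    for (L in seq_len(depth)) {
      mods <- modules_at_level(tree, L)
      for (nm in names(mods)) {
        cv <- degree_curve(mods[[nm]], metric)
        if (nrow(cv)) fam[[length(fam) + 1L]] <-
            mutate(cv, source = nm, level = L)
      }
    }
  }
  out <- bind_rows(fam)[, c("source", "level", "k", "value", "n_nodes")]
  structure(out, class = c("curve_family", class(out)), metric = metric)
}

usable_members <- function(family, k_min) {
  family %>%
    filter(.data$k >= k_min, .data$value > 0, .data$k > 0) %>%
    group_by(.data$source, .data$level) %>%
    filter(dplyr::n() >= 3L) %>%
    ungroup()
}

#' Common power-law exponent of a curve family
#'
#' Fits every member curve on log-log axes and returns the weighted mean of
#' the member exponents (weights = usable point counts) — the shared slope
#' `phi` of the family's near-parallel power-law fits.  Members with fewer
#' than 3 usable points are excluded with a warning.
#'
#' @param family A `curve_family`.
#' @param k_min Low-degree trim passed to [fit_loglog()].
#' @return A list with `phi`, and `members`: a tibble of per-member
#'   exponents, weights and the dispersion (sd) of member slopes.
#' @export
common_exponent <- function(family, k_min = 1) {
  d <- usable_members(family, k_min)
  n_excluded <- length(unique(paste(family$source))) -
    length(unique(paste(d$source)))
  if (nrow(d) == 0L) abort("no usable members", class = "hierscale_error")
  if (n_excluded > 0) {
    warn(sprintf("%d member(s) excluded (fewer than 3 usable points)",
                 n_excluded))
  }
  members <- d %>%
    group_by(.data$source, .data$level) %>%
    summarise(
      exponent = fit_loglog(dplyr::pick(dplyr::everything()))$exponent,
      weight = dplyr::n(), .groups = "drop")
  list(
    phi = sum(members$exponent * members$weight) / sum(members$weight),
    members = members,
    dispersion = if (nrow(members) > 1) sd(members$exponent) else 0
  )
}

#' One-parameter scaling collapse of a curve family
#'
#' Collapses all member curves onto the single master power law
#' `Lambda(k) = A_0 (k * xi_m)^phi`: at the fixed common slope `phi` each
#' member's amplitude `A_m` is fit by least squares in log-log space, the
#' root amplitude `A_0` sets the reference scale, and each member is shifted
#' horizontally by `xi_m = (A_m / A_0)^(1/phi)` (so `xi_root = 1`).  The
#' pooled shifted points are refit for the master exponent.
#'
#' @param family A `curve_family`.
#' @param phi Common exponent; default `NULL` estimates it with
#'   [common_exponent()].
#' @param k_min Low-degree trim.
#' @return A `scaling_result`: list with `phi`, `xi` (named vector,
#'   `xi["root"] = 1`), `pooled` (tibble `source, level, k, x, value` with
#'   `x = k * xi`), `master_fit` (a `loglog_fit`), `amplitude0`, and
#'   `n_excluded`.
#' @examples
#' fam <- curve_family(decompose_graph(rb_hierarchical(3)), "clustering")
#' res <- collapse_curves(fam)
#' res$master_fit$exponent
#' @export
collapse_curves <- function(family, phi = NULL, k_min = 1) {
  if (is.null(phi)) phi <- suppressWarnings(common_exponent(family, k_min)$phi)
  if (phi == 0) abort("phi must be nonzero", class = "hierscale_error")
  d <- usable_members(family, k_min)
  if (!"root" %in% d$source) abort("root member unusable", class = "hierscale_error")
  n_excluded <- length(unique(family$source)) - length(unique(d$source))
  # amplitude at fixed slope: log10 A_m = mean(log10 v - phi log10 k)
  amps <- d %>%
    group_by(.data$source, .data$level) %>%
    summarise(log_amp = mean(log10(.data$value) - phi * log10(.data$k)),
              .groups = "drop")
  if (any(!is.finite(amps$log_amp))) {
    abort("non-positive member amplitude", class = "hierscale_error")
  }
  a0 <- amps$log_amp[amps$source == "root"]
  xi <- setNames(10^((amps$log_amp - a0) / phi), amps$source)
  pooled <- d %>%
    mutate(x = .data$k * unname(xi[.data$source])) %>%
    arrange(.data$x) %>%
    dplyr::select("source", "level", "k", "x", "value")
  master <- fit_loglog(
    tibble(k = pooled$x, value = pooled$value))
  structure(
    list(phi = phi, xi = xi, pooled = pooled, master_fit = master,
         amplitude0 = 10^a0, n_excluded = n_excluded,
         metric = attr(family, "metric")),
    class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf(
    "<scaling_result %s> phi = %.4f, %d members, master exponent = %.4f (r2 %.3f)\n",
    x$metric %||% "", x$phi, length(x$xi), x$master_fit$exponent,
    x$master_fit$r2))
  invisible(x)
}

#' @export
tidy.scaling_result <- function(x, ...) {
  tibble(source = names(x$xi), xi = unname(x$xi))
}

#' @export
glance.scaling_result <- function(x, ...) {
  tibble(phi = x$phi, master_exponent = x$master_fit$exponent,
         master_r2 = x$master_fit$r2, n_members = length(x$xi),
         n_excluded = x$n_excluded, n_pooled = nrow(x$pooled))
}

#' Power-law existence test on collapsed data
#'
#' Runs the Clauset machinery ([pl_fit()] + [pl_gof()]) on the pooled
#' collapsed sample values; the master power law is considered plausible
#' when the returned p-value exceeds 0.1.
#'
#' @param result A `scaling_result`.
#' @param mode `"continuous"` (curve values) or `"discrete"`.
#' @param n_sims Bootstrap replicates.
#' @param seed Optional seed.
#' @return The `plfit` with its bootstrap `p_value`.
#' @export
scaled_existence_test <- function(result, mode = "continuous",
                                  n_sims = 2500L, seed = NULL) {
  stopifnot(inherits(result, "scaling_result"))
  vals <- result$pooled$value
  if (length(vals) == 0L) abort("empty pooled data", class = "hierscale_error")
  fit <- pl_fit(vals, mode = mode)
  pl_gof(fit, n_sims = n_sims, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
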