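#' Continuous power-law exponent by maximum likelihood
#'
#' For tail data `x >= x_min` drawn from a continuous power law
#' `p(x) ~ x^-alpha`, the MLE is `alpha = 1 + n / sum(log(x_i / x_min))`.
#'
#' @param x Numeric data (only values `>= x_min` are used).
#' @param x_min Lower cutoff, `> 0`.
#' @return The exponent estimate (`> 1`).
#' @export
pl_alpha_continuous <- function(x, x_min) {
  tail_x <- x[x >= x_min]
  if (length(tail_x) < 2L) abort("need >= 2 tail points", class = "hierscale_pl_error")
  s <- sum(log(tail_x / x_min))
  if (s <= 0) {
    abort("all tail points equal x_min: MLE diverges", class = "hierscale_pl_error")
  }
  1 + length(tail_x) / s
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Solves `mean(log x_i) = -zeta'(alpha, x_min) / zeta(alpha, x_min)` for the
#' tail `x >= x_min` on `alpha` in (1, 6], to tolerance 1e-6 (Hurwitz-zeta
#' likelihood for `p(x) = x^-alpha / zeta(alpha, x_min)`).
#'
#' @param x Integer-valued data.
#' @param x_min Integer lower cutoff, `>= 1`.
#' @return The exponent estimate.
#' @export
pl_alpha_discrete <- function(x, x_min) {
  tail_x <- x[x >= x_min]
  if (length(tail_x) < 2L) abort("need >= 2 tail points", class = "hierscale_pl_error")
  mlog <- mean(log(tail_x))
  f <- function(a) mlog + hzeta_dlog(a, x_min)
  lo <- 1 + 1e-4; hi <- 6
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    abort("no MLE root in (1, 6]: degenerate tail", class = "hierscale_pl_error")
  }
  uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Kolmogorov-Smirnov distance between tail data and a power-law model
#'
#' `D = sup_x |S(x) - P(x)|` over the tail `x >= x_min`, where `S` is the
#' empirical CDF of the tail and `P` the fitted model CDF (continuous:
#' `1 - (x/x_min)^(1-alpha)`; discrete: Hurwitz-zeta partial sums).
#'
#' @param x Data vector.
#' @param x_min Lower cutoff.
#' @param alpha Power-law exponent.
#' @param mode `"continuous"` or `"discrete"`.
#' @return The KS distance in `[0, 1]`.
#' @export
pl_ks <- function(x, x_min, alpha, mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  tail_x <- sort(x[x >= x_min])
  n <- length(tail_x)
  if (n == 0L) abort("empty tail", class = "hierscale_pl_error")
  if (mode == "continuous") {
    p <- 1 - (tail_x / x_min)^(1 - alpha)
    i <- seq_len(n)
    max(pmax(abs(i / n - p), abs((i - 1) / n - p)))
  } else {
    u <- unique(tail_x)
    z0 <- hzeta(alpha, x_min)
    pcdf <- function(v) 1 - hzeta(alpha, v + 1) / z0
    s_at <- cumsum(tabulate(match(tail_x, u), length(u))) / n
    d1 <- abs(s_at - pcdf(u))
    # between observed jumps the empirical CDF is flat while the model grows;
    # the sup can sit at the integer just before the next jump
    if (length(u) > 1L) {
      d2 <- abs(s_at[-length(u)] - pcdf(u[-1] - 1))
      max(d1, d2)
    } else {
      max(d1)
    }
  }
}

#' Fit a power law with the Clauset lower-bound selection
#'
#' For each candidate `x_min` among the unique data values (candidates
#' leaving fewer than 5 tail points excluded), estimates `alpha` by maximum
#' likelihood and computes the KS distance `D`; returns the fit minimizing
#' `D` (ties resolve to the smallest `x_min`).  When the data hold many
#' unique values the candidate set is thinned to `max_candidates`
#' quantile-spaced values for tractability.
#'
#' @param x Data vector (positive; integers for `mode = "discrete"`).
#' @param mode `"continuous"` or `"discrete"`.
#' @param x_min Optional fixed lower bound: skips the scan and fits the tail
#'   at this cutoff.
#' @param max_candidates Cap on the number of scanned candidates (default
#'   250).
#' @return A `plfit` object: list with `x_min`, `alpha`, `ks_D`, `n_tail`,
#'   `n`, `mode`, `p_value` (`NA` until [pl_gof()] is run) and the data.
#' @examples
#' x <- rpl_continuous(500, alpha = 2.5, x_min = 1)
#' pl_fit(x, mode = "continuous")
#' @export
pl_fit <- function(x, mode = c("continuous", "discrete"),
                   x_min = NULL, max_candidates = 250L) {
  mode <- match.arg(mode)
  stopifnot(all(x > 0))
  if (mode == "discrete") stopifnot(all(x == round(x)))
  fixed <- !is.null(x_min)
  new_fit <- function(xm, alpha, D) {
    structure(
      list(x_min = xm, alpha = alpha, ks_D = D,
           n_tail = sum(x >= xm), n = length(x), mode = mode,
           fixed_xmin = fixed, p_value = NA_real_, data = x),
      class = "plfit")
  }
  alpha_fun <- if (mode == "continuous") pl_alpha_continuous else pl_alpha_discrete
  if (fixed) {
    a <- alpha_fun(x, x_min)
    return(new_fit(x_min, a, pl_ks(x, x_min, a, mode)))
  }
  sx <- sort(x)
  n <- length(sx)
  first_idx <- which(!duplicated(sx))   # position of each unique value
  if (length(first_idx) < 5L) {
    abort("need >= 5 distinct values to scan x_min", class = "hierscale_pl_error")
  }
  cand_idx <- first_idx[n - first_idx + 1L >= 5L]
  if (length(cand_idx) == 0L) cand_idx <- first_idx[[1]]
  if (length(cand_idx) > max_candidates) {
    ii <- unique(round(seq(1L, length(cand_idx),
                           length.out = max_candidates)))
    cand_idx <- cand_idx[ii]
  }
  suff_log <- rev(cumsum(rev(log(sx))))
  best <- NULL
  for (i in cand_idx) {
    xm <- sx[[i]]
    m <- n - i + 1L
    tail_x <- sx[i:n]
    if (mode == "continuous") {
      s <- suff_log[[i]] - m * log(xm)
      if (s <= 0) next
      a <- 1 + m / s
      p <- 1 - (tail_x / xm)^(1 - a)
      jj <- seq_len(m)
      D <- max(pmax(abs(jj / m - p), abs((jj - 1) / m - p)))
    } else {
      mlog <- suff_log[[i]] / m
      f <- function(al) mlog + hzeta_dlog(al, xm)
      flo <- f(1 + 1e-4); fhi <- f(6)
      if (is.na(flo) || is.na(fhi) || flo * fhi > 0) next
      a <- uniroot(f, c(1 + 1e-4, 6), tol = 1e-6)$root
      D <- pl_ks(tail_x, xm, a, "discrete")
    }
    if (is.null(best) || D < best$ks_D) best <- new_fit(xm, a, D)
  }
  if (is.null(best)) abort("no candidate x_min admitted a fit",
                           class = "hierscale_pl_error")
  best
}

#' Bootstrap goodness-of-fit p-value for a power-law fit
#'
#' Semi-parametric bootstrap: each synthetic dataset of size `n` draws each
#' point with probability `n_tail/n` from the fitted model (tail `>= x_min`)
#' and otherwise resamples uniformly from the empirical values below
#' `x_min`.  Every synthetic set is refit from scratch (`x_min` and `alpha`
#' re-estimated) giving a distance `D_s`; the p-value is the fraction of
#' `D_s` exceeding the empirical `D_m`.  The power law is considered
#' plausible when `p > 0.1`.  The refit mirrors how the empirical fit was
#' obtained: a fit produced with a fixed `x_min` is bootstrapped with the
#' cutoff held fixed (parametric KS bootstrap; `alpha` re-estimated), while
#' a scanned fit re-runs the full `x_min` scan on every synthetic set.
#'
#' @param fit A `plfit` from [pl_fit()].
#' @param n_sims Number of bootstrap datasets (default 2500).
#' @param seed Optional integer seed.
#' @param max_candidates Candidate cap used for the refits.
#' @return The updated `plfit` with `p_value` and `n_sims` filled in.
#' @export
pl_gof <- function(fit, n_sims = 2500L, seed = NULL, max_candidates = 250L) {
  stopifnot(inherits(fit, "plfit"), n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- fit$data
  n <- length(x)
  below <- x[x < fit$x_min]
  p_tail <- fit$n_tail / n
  rtail <- function(m) {
    if (fit$mode == "continuous") rpl_continuous(m, fit$alpha, fit$x_min)
    else rpl_discrete(m, fit$alpha, fit$x_min)
  }
  d_s <- vapply(seq_len(n_sims), function(s) {
    m_tail <- rbinom(1L, n, p_tail)
    syn <- c(rtail(m_tail),
             if (n - m_tail > 0L) sample(below, n - m_tail, replace = TRUE))
    refit <- tryCatch(
      pl_fit(syn, mode = fit$mode,
                    x_min = if (isTRUE(fit$fixed_xmin)) fit$x_min else NULL,
                    max_candidates = max_candidates),
      error = function(e) NULL)
    if (is.null(refit)) NA_real_ else refit$ks_D
  }, numeric(1))
  fit$p_value <- mean(d_s > fit$ks_D, na.rm = TRUE)
  fit$n_sims <- n_sims
  fit
}

#' @export
print.plfit <- function(x, ...) {
  cat(sprintf(
    "<plfit %s> x_min = %g, alpha = %.4f, KS D = %.4f, n_tail = %d/%d%s\n",
    x$mode, x$x_min, x$alpha, x$ks_D, x$n_tail, x$n,
    if (is.na(x$p_value)) "" else sprintf(", p = %.4f", x$p_value)))
  invisible(x)
}

#' @export
tidy.plfit <- function(x, ...) {
  tibble(term = c("x_min", "alpha"), estimate = c(x$x_min, x$alpha))
}

#' @export
glance.plfit <- function(x, ...) {
  tibble(x_min = x$x_min, alpha = x$alpha, ks_D = x$ks_D,
         p_value = x$p_value, n = x$n, n_tail = x$n_tail, mode = x$mode)
}

#' Least-squares power-law fit of a curve on log-log axes
#'
#' Ordinary least squares of `log10(value)` on `log10(k)` for a
#' degree-conditioned curve; points with `k < k_min` or non-positive value
#' are dropped (count reported).  This is the regression exponent used for
#' plotted curves; existence testing uses the Clauset machinery instead.
#'
#' @param curve A tibble with columns `k` and `value` (e.g. from
#'   [degree_curve()]), or a two-column data frame.
#' @param k_min Smallest abscissa retained (default 1 = no trimming).
#' @return A `loglog_fit`: list with `exponent`, `intercept` (log10 scale),
#'   `stderr`, `r2`, `n_used`, `n_dropped`.
#' @examples
#' fit_loglog(tibble::tibble(k = 1:10, value = 4 * (1:10)^-0.5))
#' @export
fit_loglog <- function(curve, k_min = 1) {
  stopifnot(all(c("k", "value") %in% names(curve)))
  keep <- curve$k >= k_min & curve$value > 0 & curve$k > 0
  n_dropped <- sum(!keep)
  d <- curve[keep, ]
  if (nrow(d) < 3L) abort("fewer than 3 usable points", class = "hierscale_pl_error")
  fit <- lm(log10(value) ~ log10(k), data = d)
  s <- suppressWarnings(summary(fit))
  structure(
    list(exponent = unname(coef(fit)[[2]]),
         intercept = unname(coef(fit)[[1]]),
         stderr = unname(s$coefficients[2, 2]),
         r2 = s$r.squared,
         n_used = nrow(d), n_dropped = n_dropped),
    class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "<loglog_fit> exponent = %.4f (se %.4f), r2 = %.4f, n = %d (%d dropped)\n",
    x$exponent, x$stderr, x$r2, x$n_used, x$n_dropped))
  invisible(x)
}

#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble(term = c("exponent", "intercept"),
         estimate = c(x$exponent, x$intercept),
         std.error = c(x$stderr, NA_real_))
}

#' @export
glance.loglog_fit <- function(x, ...) {
  tibble(exponent = x$exponent, intercept = x$intercept, stderr = x$stderr,
         r2 = x$r2, n_used = x$n_used, n_dropped = x$n_dropped)
}
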