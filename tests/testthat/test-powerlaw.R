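test_that("Hurwitz zeta matches reference values", {
  # reference values computed with an independent implementation
  ref <- rbind(
    c(2.5, 1, 1.34148725725092),
    c(2.5, 10, 0.0227286991945345),
    c(1.5, 3, 1.25882195809221),
    c(3.2, 7, 0.00734829789803123),
    c(2.0, 1, pi^2 / 6),
    c(1.1, 2, 9.5844484649508))
  for (i in seq_len(nrow(ref))) {
    expect_equal(hierscale:::hzeta(ref[i, 1], ref[i, 2]), ref[i, 3],
                 tolerance = 1e-9)
  }
})

test_that("continuous MLE matches the closed form and errors on flat tails", {
  expect_equal(pl_alpha_continuous(c(2, 4, 8), 2),
               1 + 3 / (log(2) + log(4)))
  # constructed identity: sum(log(x/xmin)) = n gives alpha = 2
  x <- 3 * exp(c(0.5, 1, 1.5))
  expect_equal(pl_alpha_continuous(x, 3), 2)
  expect_error(pl_alpha_continuous(c(2, 2, 2), 2), "diverges")
})

test_that("discrete MLE recovers the generator exponent", {
  x <- rpl_discrete(30000, 2.5, 1, seed = 101)
  expect_equal(pl_alpha_discrete(x, 1), 2.5, tolerance = 0.05)
  expect_error(pl_alpha_discrete(c(5, 5, 5), 5), "degenerate")
  # large-x_min discrete tail is close to the continuous estimate
  x2 <- rpl_discrete(20000, 2.5, 50, seed = 102)
  expect_lt(abs(pl_alpha_discrete(x2, 50) - pl_alpha_continuous(x2, 50)),
            0.05)
})

test_that("KS distance behaves at plug-in quantiles and boundaries", {
  n <- 200; alpha <- 2.5; xmin <- 1
  # exact model quantiles at (i - 0.5)/n
  q <- xmin * (1 - (seq_len(n) - 0.5) / n)^(-1 / (alpha - 1))
  expect_lte(pl_ks(q, xmin, alpha, "continuous"), 0.5 / n + 1e-9)
  expect_equal(pl_ks(1, 1, 2.5, "continuous"), 1)
  set.seed(7)
  xe <- rexp(1000, 1) + 1
  a <- pl_alpha_continuous(xe, 1)
  expect_gt(pl_ks(xe, 1, a, "continuous"), 0.1)
})

test_that("x_min scanning minimizes D, breaks ties low and resists noise", {
  # exactly 5 distinct values: single candidate evaluated
  f <- pl_fit(c(1, 2, 3, 4, 5), mode = "discrete")
  expect_equal(f$x_min, 1)
  expect_equal(f$n_tail, 5)
  expect_error(pl_fit(c(1, 1, 2, 2, 3), mode = "discrete"),
               "distinct")
  # invariance to ordering and to duplicated below-tail values
  x <- rpl_continuous(400, 2.5, 10, seed = 55)
  x <- c(runif(400, 1, 10), x)
  f1 <- pl_fit(x, "continuous")
  f2 <- pl_fit(sample(x), "continuous")
  f3 <- pl_fit(c(x, runif(50, 1, 5)), "continuous")
  expect_equal(f1$x_min, f2$x_min)
  expect_equal(f1$alpha, f2$alpha)
  expect_gt(f3$x_min, 5)  # extra low-end noise cannot drag x_min down
  # noisy-head recovery near the true cutoff
  expect_gte(f1$x_min, 6)
  expect_lte(f1$x_min, 14)
  # ks_D is recomputable from the stored fit
  expect_equal(f1$ks_D, pl_ks(x, f1$x_min, f1$alpha, "continuous"))
})

test_that("bootstrap p-value separates power-law from exponential data", {
  x <- rpl_continuous(300, 2.5, 1, seed = 9)
  fit <- pl_fit(x, "continuous")
  fit <- pl_gof(fit, n_sims = 150, seed = 10)
  expect_gt(fit$p_value, 0.1)
  set.seed(11)
  xe <- rexp(1000, 1) + 1
  fe <- pl_fit(xe, "continuous")
  fe <- pl_gof(fe, n_sims = 150, seed = 12)
  expect_lt(fe$p_value, 0.1)
})

test_that("log-log regression recovers exact and noisy slopes", {
  cv <- tibble::tibble(k = 1:10, value = (1:10)^-1)
  f <- fit_loglog(cv)
  expect_equal(f$exponent, -1)
  expect_equal(f$r2, 1)
  cv2 <- tibble::tibble(k = 1:10, value = 4 * (1:10)^-0.5)
  f2 <- fit_loglog(cv2)
  expect_equal(f2$exponent, -0.5)
  expect_equal(f2$intercept, log10(4))
  # refitting its own fitted line returns the same exponent
  line <- tibble::tibble(k = 2:20,
                         value = 10^f2$intercept * (2:20)^f2$exponent)
  expect_equal(fit_loglog(line)$exponent, f2$exponent, tolerance = 1e-12)
  set.seed(3)
  reps <- replicate(20, {
    k <- 1:30
    v <- 10^(0.3 - 0.65 * log10(k) + rnorm(30, 0, 0.05))
    fit_loglog(tibble::tibble(k = k, value = v))$exponent
  })
  expect_lt(abs(mean(reps) + 0.65), 0.05)
  expect_error(fit_loglog(tibble::tibble(k = 1:2, value = c(1, 2))),
               "3 usable")
  # zero values are dropped with a count
  cvz <- tibble::tibble(k = 1:5, value = c(1, 0.5, 0, 0.25, 0.2))
  expect_equal(fit_loglog(cvz)$n_dropped, 1)
})

test_that("power-law fit tidiers expose the fit", {
  x <- rpl_continuous(200, 2.5, 1, seed = 2)
  f <- pl_fit(x, "continuous")
  gl <- glance(f)
  expect_named(gl, c("x_min", "alpha", "ks_D", "p_value", "n", "n_tail",
                     "mode"))
  expect_equal(gl$n, 200)
  expect_equal(nrow(tidy(f)), 2)
})
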