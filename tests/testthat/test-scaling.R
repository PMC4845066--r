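make_family <- function(members) {
  # members: named list of tibbles (k, value); first entry is the root
  out <- dplyr::bind_rows(lapply(seq_along(members), function(i) {
    dplyr::mutate(members[[i]],
                  source = names(members)[[i]],
                  level = if (names(members)[[i]] == "root") 0L else 1L,
                  n_nodes = 1L)
  }))
  structure(out, class = c("curve_family", class(out)), metric = "test")
}

test_that("parallel exact lines give the common slope", {
  k <- 1:12
  fam <- make_family(list(root = tibble::tibble(k = k, value = k^-1),
                          m1 = tibble::tibble(k = k, value = 5 * k^-1)))
  expect_equal(common_exponent(fam)$phi, -1)
  fam2 <- make_family(list(root = tibble::tibble(k = k, value = k^-0.9),
                           m1 = tibble::tibble(k = k, value = k^-1.1)))
  expect_equal(common_exponent(fam2)$phi, -1, tolerance = 1e-10)
})

test_that("collapse reproduces the exact algebra 4k^-1 = (k/4)^-1", {
  k <- 1:10
  fam <- make_family(list(root = tibble::tibble(k = k, value = k^-1),
                          m1 = tibble::tibble(k = k, value = 4 * k^-1)))
  res <- collapse_curves(fam, phi = -1)
  expect_equal(res$xi[["root"]], 1)
  expect_equal(res$xi[["m1"]], 1 / 4)
  # pooled points lie exactly on value = x^-1
  expect_equal(res$pooled$value, res$pooled$x^-1)
  expect_equal(res$master_fit$exponent, -1)
})

test_that("a single-member family collapses to itself", {
  k <- 1:10
  fam <- make_family(list(root = tibble::tibble(k = k, value = 2 * k^-0.7)))
  res <- collapse_curves(fam)
  expect_equal(unname(res$xi), 1)
  expect_equal(res$master_fit$exponent, -0.7)
  expect_equal(nrow(res$pooled), 10)
})

test_that("collapse is scale-equivariant and round-trips member lines", {
  set.seed(8)
  k <- 1:15
  mk <- function(amp) tibble::tibble(k = k, value = amp * k^-0.8)
  fam <- make_family(list(root = mk(1), m1 = mk(3), m2 = mk(0.5)))
  res <- collapse_curves(fam, phi = -0.8)
  # multiplying one member by c multiplies its xi by c^(1/phi)
  fam2 <- make_family(list(root = mk(1), m1 = mk(3 * 2), m2 = mk(0.5)))
  res2 <- collapse_curves(fam2, phi = -0.8)
  expect_equal(res2$xi[["m1"]], res$xi[["m1"]] * 2^(1 / -0.8))
  expect_equal(res2$xi[["m2"]], res$xi[["m2"]])
  expect_equal(res2$master_fit$exponent, res$master_fit$exponent,
               tolerance = 1e-10)
  # reconstructing each member from (master amplitude, xi) recovers its line
  for (m in c("m1", "m2")) {
    amp_m <- res$amplitude0 * res$xi[[m]]^res$phi
    member <- fam[fam$source == m, ]
    expect_equal(member$value, amp_m * member$k^res$phi)
  }
})

test_that("noisy 20-member parallel families recover the slope", {
  set.seed(13)
  k <- 1:25
  members <- lapply(1:20, function(i) {
    amp <- 10^runif(1, -0.5, 0.5)
    tibble::tibble(k = k,
                   value = amp * k^-0.7 * 10^rnorm(25, 0, 0.1))
  })
  names(members) <- c("root", paste0("m", 1:19))
  fam <- make_family(members)
  ce <- common_exponent(fam)
  expect_equal(ce$phi, -0.7, tolerance = 0.05)
  res <- collapse_curves(fam)
  expect_equal(res$master_fit$exponent, -0.7, tolerance = 0.05)
  # residual scatter of the pooled fit is no worse than a typical member
  member_r2 <- min(vapply(split(fam, fam$source),
                          function(d) fit_loglog(d)$r2, numeric(1)))
  expect_gte(res$master_fit$r2, member_r2 - 0.05)
})

test_that("existence testing accepts collapsed power laws, rejects exponentials", {
  set.seed(17)
  k <- 1:40
  fam <- make_family(list(
    root = tibble::tibble(k = k, value = rpl_continuous(40, 3, 1)),
    m1 = tibble::tibble(k = k, value = 2 * rpl_continuous(40, 3, 1))))
  res <- collapse_curves(fam, phi = -1)
  p <- scaled_existence_test(res, n_sims = 100, seed = 23)$p_value
  expect_gt(p, 0.1)
  fam2 <- make_family(list(
    root = tibble::tibble(k = k, value = rexp(40, 1) + 1),
    m1 = tibble::tibble(k = k, value = rexp(40, 1) + 1)))
  res2 <- collapse_curves(fam2, phi = -1)
  p2 <- scaled_existence_test(res2, n_sims = 100, seed = 24)$p_value
  expect_lt(p2, 0.25)
})

test_that("curve families built from a module tree carry the root reference", {
  tr <- decompose_graph(rb_hierarchical(2))
  fam <- curve_family(tr, "clustering")
  expect_true("root" %in% fam$source)
  expect_equal(unique(fam$level[fam$source == "root"]), 0L)
  expect_true(all(fam$level[fam$source != "root"] >= 1))
})
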