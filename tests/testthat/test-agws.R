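test_that("qr_points ranks s-values with midpoint plotting positions", {
  res <- tibble::tibble(chrom = rep("7", 4), s = c(1, 3, 2, 4))
  qr <- qr_points(res, "7", min_results = 4)
  expect_equal(qr$x, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(qr$s, 1:4)
  expect_error(qr_points(res, "7", min_results = 10), "need >=")
  # ties keep x strictly increasing
  res2 <- tibble::tibble(chrom = "1", s = rep(2, 12))
  qr2 <- qr_points(res2, "1", min_results = 10)
  expect_true(all(diff(qr2$x) > 0))
})

test_that("convex_fit reproduces a straight line exactly", {
  x <- (1:50 - 0.5) / 50
  fit <- convex_fit(x, 3 * x, trim_top = 0)
  expect_lt(max(abs(fit$fitted - 3 * x)), 1e-6)
  expect_equal(fit$apex, 3 * max(x), tolerance = 1e-6)
})

test_that("convex_fit matches the quadratic-programming oracle", {
  # fixture: noisy quadratic, 50 points; oracle values computed once with
  # an SLSQP solve of min ||f - s||^2 s.t. diff(f) >= 0, diff(f, 2) >= 0
  set.seed(7)
  x <- (1:50 - 0.5) / 50
  s <- sort(9 * x^2 + rnorm(50, sd = 0.4))
  fit <- convex_fit(x, s, trim_top = 0, n_knots = 50)
  oracle <- c(`1` = -0.43036652000389, `10` = 0.57998216349523,
              `25` = 2.36344358167126, `40` = 5.57104264446525,
              `50` = 9.19332879685113)
  for (i in names(oracle)) {
    expect_lt(abs(fit$fitted[as.integer(i)] - oracle[[i]]), 1e-3)
  }
  expect_lt(abs(fit$apex - 9.19332879685113), 1e-3)
  # discrete convexity and monotonicity on the full grid
  expect_true(all(diff(fit$fitted) >= -1e-9))
  expect_true(all(diff(fit$fitted, differences = 2) >= -1e-8))
})

test_that("trimming keeps the apex stable under a top-rank outlier", {
  set.seed(8)
  x <- (1:100 - 0.5) / 100
  s <- sort(4 * x^2 + rnorm(100, sd = 0.2))
  clean <- convex_fit(x, s, trim_top = 0.05)
  s_out <- s
  s_out[100] <- s_out[100] + 25
  dirty <- convex_fit(x, s_out, trim_top = 0.05)
  expect_lt(abs(dirty$apex - clean$apex) / clean$apex, 0.05)
})

test_that("count_outliers applies the tolerance literally", {
  x <- (1:20 - 0.5) / 20
  s <- sort(2 * x)
  fit <- convex_fit(x, s, trim_top = 0)
  expect_identical(count_outliers(x, s, fit, tol = 0.5), 0L)
  s2 <- s; s2[20] <- fit$fitted[20] + 1.0   # top point stays sorted
  expect_identical(count_outliers(x, s2, fit, tol = 0.5), 1L)
  s3 <- fit$fitted + 0.4
  expect_identical(count_outliers(x, s3, fit, tol = 0.5), 0L)
})

make_null_results <- function(n_chrom, n_per, seed, shift = 0) {
  set.seed(seed)
  tibble::tibble(
    chrom = rep(as.character(seq_len(n_chrom)), each = n_per),
    s = -log10(runif(n_chrom * n_per)) + shift,
    analysis = "ss"
  )
}

test_that("identical chromosomes give agws equal to the common apex", {
  res1 <- make_null_results(1, 300, seed = 51)
  res <- tibble::tibble(chrom = rep(as.character(1:6), each = 300),
                        s = rep(res1$s, 6), analysis = "ss")
  a <- agws_cutoff(res)
  expect_equal(length(unique(round(tidy(a)$apex, 10))), 1L)
  expect_equal(a$agws, tidy(a)$apex[1])
  expect_equal(a$agws_half, a$agws / 2)
  expect_identical(sum(tidy(a)$selected), 3L)
})

test_that("agws is invariant to chromosome relabeling and row order", {
  res <- make_null_results(8, 200, seed = 52)
  a1 <- agws_cutoff(res)$agws
  scramble <- res[sample(nrow(res)), ]
  expect_equal(agws_cutoff(scramble)$agws, a1)
  relabel <- res
  relabel$chrom <- paste0("chr", relabel$chrom)
  expect_equal(agws_cutoff(relabel)$agws, a1)
})

test_that("adding a constant to every s shifts agws by exactly that constant", {
  res <- make_null_results(6, 150, seed = 53)
  a0 <- agws_cutoff(res)$agws
  res_shift <- res
  res_shift$s <- res_shift$s + 1.7
  expect_equal(agws_cutoff(res_shift)$agws, a0 + 1.7, tolerance = 1e-8)
})

test_that("chromosomes carrying signal are excluded from the null estimate", {
  # half the chromosomes get implanted outliers above any convex trend
  set.seed(54)
  res <- make_null_results(8, 250, seed = 54)
  spiked <- as.character(1:4)
  idx <- res$chrom %in% spiked
  bump <- ave(seq_len(nrow(res)), res$chrom, FUN = seq_along) > 235
  res$s[idx & bump] <- res$s[idx & bump] + 6
  a <- agws_cutoff(res)
  sel <- tidy(a)$chrom[tidy(a)$selected]
  expect_identical(sort(sel), sort(as.character(5:8)))
})

test_that("agws_cutoff validates its inputs and exports cleanly", {
  res <- make_null_results(3, 100, seed = 55)
  expect_error(agws_cutoff(res), ">= 4 chromosomes")
  res2 <- dplyr::bind_rows(make_null_results(5, 100, seed = 56),
                           tibble::tibble(chrom = "99", s = 1:3,
                                          analysis = "ss"))
  expect_warning(a <- agws_cutoff(res2), "excluding")
  expect_identical(nrow(tidy(a)), 5L)
  g <- glance(a)
  expect_identical(g$n_selected, 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_agws_json(a, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$agws, a$agws)
  expect_equal(length(j$chromosomes), 5L)
  # plot data covers every chromosome point
  pd <- qr_plot_data(a)
  expect_identical(nrow(pd), 500L)
})
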