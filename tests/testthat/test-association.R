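test_that("u-scores count comparisons won minus lost and sum to zero", {
  expect_identical(u_scores(snp_ordering(c(0, 1, 2), 1)), c(-2L, 0L, 2L))
  expect_identical(u_scores(ordering_matrix_all_eq(4)), rep(0L, 4))
  set.seed(21)
  for (i in 1:50) {
    w <- random_ordering(sample(3:12, 1))
    expect_identical(sum(u_scores(w)), 0L)
  }
})

test_that("score test matches the hand-enumerated exact distribution", {
  u <- c(-2L, 0L, 2L)
  res <- score_test(u, c(0, 0, 1), method = "exact")
  expect_equal(res$t, 2)
  expect_equal(res$p, 2 / 3)
  nrm <- score_test(u, c(0, 0, 1), method = "normal")
  expect_equal(nrm$var_t, (1 * 2 / (3 * 2)) * 8)
  expect_equal(nrm$statistic, 2 / sqrt(8 / 3), tolerance = 1e-12)
})

test_that("degenerate u-scores give p = 1 with a non-informative flag", {
  res <- score_test(rep(0L, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(res$p, 1)
  expect_true(res$non_informative)
})

test_that("exact score test reproduces the enumeration oracle", {
  set.seed(22)
  for (i in 1:25) {
    w <- random_ordering(12)
    u <- u_scores(w)
    if (sum(u^2) == 0) next
    status <- sample(rep(0:1, each = 6))
    ex <- score_test(u, status, "exact")
    oracle <- exact_perm_p(u, 6)(sum(u[status == 1]))
    expect_equal(ex$p, oracle)
  }
  expect_error(score_test(rep(c(-1L, 1L), 11), rep(0:1, 11), "exact"),
               "n <= 20")
})

test_that("normal approximation tracks the permutation law at n = 12", {
  # fully decided orderings; agreement measured on the mid-p scale, which
  # splits the probability atom at |T| that an inclusive tail definition
  # assigns entirely to the tail
  set.seed(22)
  for (i in 1:25) {
    u <- sample(seq(-11L, 11L, by = 2L))
    status <- sample(rep(0:1, each = 6))
    p_norm <- score_test(u, status, "normal")$p
    t_obs <- sum(u[status == 1])
    t_all <- colSums(matrix(u[utils::combn(12, 6)], nrow = 6))
    p_mid <- mean(abs(t_all) > abs(t_obs) + 1e-9) +
      0.5 * mean(abs(abs(t_all) - abs(t_obs)) <= 1e-9)
    expect_lt(abs(p_norm - p_mid), 0.05)
  }
})

test_that("single-SNP scan agrees with the explicit ordering route", {
  set.seed(23)
  d <- matrix(sample(c(0:2, NA), 50 * 8, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), 50, 8)
  g <- toy_genotypes(d)
  status <- sample(rep(0:1, 25))
  res <- single_snp_gwas(g, status)
  for (j in 1:8) {
    st <- score_test(u_scores(snp_ordering(d[, j], 1)), status)
    row <- res[res$snp_id == sprintf("snp%02d", j), ]
    expect_equal(row$z, st$statistic)
    expect_equal(row$p, st$p)
  }
})

test_that("perfectly separating SNP attains the permutation minimum", {
  # all cases homozygous minor, all controls homozygous major
  d <- cbind(rep(c(2L, 0L), c(5, 5)))
  status <- rep(c(1, 0), c(5, 5))
  u <- u_scores(snp_ordering(d[, 1], 1))
  res <- score_test(u, status, "exact")
  expect_equal(res$p, 2 / choose(10, 5))
})

test_that("monomorphic SNPs are flagged non-informative", {
  g <- toy_genotypes(cbind(rep(0L, 10), rep(1L, 10), c(0:2, rep(0L, 7))))
  res <- single_snp_gwas(g, rep(0:1, 5))
  expect_identical(res$flags[res$snp_id %in% c("snp01", "snp02")],
                   rep("non_informative", 2))
  expect_identical(res$flags[res$snp_id == "snp03"], "")
})

test_that("candidate enumeration matches the combinatorial count", {
  coh <- small_cohort()
  g <- coh$genotypes
  # interior SNP of a block, max_window 1: the single +1 candidate
  ctr <- 3L
  expect_identical(nrow(candidate_scan(g, coh$phenotypes, ctr,
                                       max_window = 1)), 1L)
  # max_window 2: windows {k}, {k-1,k}, {k,k+1}; 1 + 4 + 4 candidates
  c2 <- candidate_scan(g, coh$phenotypes, ctr, max_window = 2)
  expect_identical(nrow(c2), 9L)
  expect_identical(sum(c2$win_len == 1), 1L)
  expect_identical(sum(c2$win_len == 2), 8L)
  # clipped at the chromosome start: only right-extending windows
  c_edge <- candidate_scan(g, coh$phenotypes, 1L, max_window = 2)
  expect_identical(nrow(c_edge), 5L)
  expect_true(all(c_edge$win_start == 1L))
})

test_that("windows never cross spacer SNPs", {
  coh <- small_cohort()
  g <- insert_block_spacers(coh$genotypes, coh$ld_blocks, max_window = 4)
  last_in_block1 <- max(which(g$snps$id |> startsWith("b001")))
  cand <- candidate_scan(g, coh$phenotypes, last_in_block1, max_window = 4)
  spans <- mapply(function(a, l) any(g$snps$is_spacer[a:(a + l - 1)]),
                  cand$win_start, cand$win_len)
  expect_false(any(spans))
  expect_true(all(cand$win_start + cand$win_len - 1 <= last_in_block1))
})

test_that("select_best applies dominance then the documented tie-breaks", {
  one <- tibble::tibble(s = 5, ic = 0.9, polarity = "1")
  expect_identical(select_best(one)$s, 5)
  # A dominates B
  ab <- tibble::tibble(s = c(5, 4), ic = c(0.9, 0.8), polarity = c("1", "1"))
  expect_equal(select_best(ab)$s, 5)
  expect_equal(select_best(ab[2:1, ])$s, 5)   # order-invariant
  # neither dominates: both score 0, tie-break to higher IC
  tie <- tibble::tibble(s = c(5, 4), ic = c(0.5, 0.9), polarity = c("1", "1"))
  expect_equal(select_best(tie)$ic, 0.9)
  expect_equal(select_best(tie[2:1, ])$ic, 0.9)
})

test_that("dominance scores are the net count of dominated candidates", {
  s <- c(5, 4, 3, 3)
  ic <- c(0.9, 0.8, 0.99, 0.8)
  # hand count: 1 dominates 2 and 4 but not 3 (higher ic); 3 dominates only
  # 4; 4 is dominated by everything
  expect_identical(mugwas:::dominance_scores(s, ic), c(2L, 0L, 1L, -3L))
})

test_that("the scan selects exactly one result per non-spacer center", {
  coh <- small_cohort(risk_model = "dominant")
  g <- insert_block_spacers(coh$genotypes, coh$ld_blocks, max_window = 3)
  res <- mu_gwas(g, coh$phenotypes, max_window = 3)
  expect_identical(nrow(res), sum(!g$snps$is_spacer))
  expect_identical(anyDuplicated(res$snp_id), 0L)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$ic >= 0 & res$ic <= 1))
  expect_true(all(res$s >= 0))
})

test_that("fast scan agrees with the explicit ordering-matrix route", {
  coh <- small_cohort(seed = 77)
  g <- insert_block_spacers(coh$genotypes, coh$ld_blocks, max_window = 3)
  status <- coh$phenotypes$status
  for (ctr in which(!g$snps$is_spacer)[c(1, 4, 9, 17)]) {
    cand <- candidate_scan(g, coh$phenotypes, ctr, max_window = 3)
    for (i in seq_len(nrow(cand))) {
      idx <- cand$win_start[i]:(cand$win_start[i] + cand$win_len[i] - 1)
      pol <- as.integer(strsplit(cand$polarity[i], ",")[[1]])
      w <- window_ordering(g, idx, pol)
      st <- score_test(u_scores(w), status)
      expect_equal(cand$ic[i], information_content(w), tolerance = 1e-12)
      expect_equal(cand$z[i], st$statistic, tolerance = 1e-9)
      expect_equal(cand$p[i], st$p, tolerance = 1e-12)
    }
    best_r <- select_best(cand)
    best_cpp <- mu_gwas(g, coh$phenotypes, max_window = 3)
    row <- best_cpp[best_cpp$snp_id == g$snps$id[ctr], ]
    expect_identical(row$window_snps, best_r$window_snps)
    expect_identical(row$polarity, best_r$polarity)
  }
})
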