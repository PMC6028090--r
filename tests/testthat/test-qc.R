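test_that("filter_snps drops monomorphic, rare and badly called SNPs", {
  d <- cbind(rep(0L, 20),                      # monomorphic
             c(rep(NA_integer_, 10), rep(c(0L, 2L), 5)),  # 50% missing
             rep(c(0L, 1L), 10))               # clean, MAF 0.25
  g <- toy_genotypes(d)
  out <- suppressMessages(filter_snps(g, maf_min = 0.01, callrate_min = 0.9))
  expect_identical(out$snps$id, "snp03")
  expect_error(suppressMessages(filter_snps(toy_genotypes(cbind(rep(0L, 4))))),
               "no informative")
})

test_that("filtering removes the analytic fraction of a uniform MAF spectrum", {
  # MAF ~ Uniform(0, 0.5): expected fraction below 0.05 is 0.10
  set.seed(41)
  n <- 400
  maf <- runif(1000, 0, 0.5)
  d <- sapply(maf, function(f) rbinom(n, 2, f))
  # recode columns drifting past 0.5 so the sample MAF convention holds
  g <- toy_genotypes(d)
  out <- suppressMessages(filter_snps(g, maf_min = 0.05, callrate_min = 0.5))
  removed <- 1 - ncol(out$dosages) / 1000
  expect_lt(abs(removed - 0.10), 0.03)
})

test_that("filter_snps and prune_adjacent_ld are idempotent", {
  coh <- small_cohort(seed = 5)
  g1 <- suppressMessages(filter_snps(coh$genotypes, 0.1, 0.95))
  g2 <- suppressMessages(filter_snps(g1, 0.1, 0.95))
  expect_identical(g2$snps, g1$snps)
  p1 <- suppressMessages(prune_adjacent_ld(g1, 0.8))
  p2 <- suppressMessages(prune_adjacent_ld(p1, 0.8))
  expect_identical(p2$snps, p1$snps)
})

test_that("neighbor-LD pruning scans left to right against the last kept SNP", {
  x <- rep(c(0L, 1L, 2L), 10)
  y <- sample(rep(c(0L, 1L, 2L), 10))
  # identical neighbors: second dropped
  g <- toy_genotypes(cbind(x, x, y))
  out <- suppressMessages(prune_adjacent_ld(g, 0.95))
  expect_identical(out$snps$id, c("snp01", "snp03"))
  # chain: snp2 ~ snp1 (dropped), snp3 then compared to snp1 and dropped too
  g3 <- toy_genotypes(cbind(x, x, x))
  out3 <- suppressMessages(prune_adjacent_ld(g3, 0.95))
  expect_identical(out3$snps$id, "snp01")
  # independent columns survive
  set.seed(42)
  a <- sample(0:2, 60, replace = TRUE)
  b <- sample(0:2, 60, replace = TRUE)
  g2 <- toy_genotypes(cbind(a, b))
  expect_identical(ncol(suppressMessages(
    prune_adjacent_ld(g2, 0.95))$dosages), 2L)
})

test_that("block spacers defeat every window up to max_window", {
  d <- matrix(rep(c(0L, 1L, 2L), 6), 3, 6)
  g <- genotype_matrix(
    d, tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L,
                                           5000L, 5100L, 5200L),
                      id = paste0("s", 1:6)))
  blocks <- tibble::tibble(chrom = "1", start = c(0L, 4900L),
                           end = c(400L, 5300L), name = c("b1", "b2"))
  out <- insert_block_spacers(g, blocks, max_window = 6)
  expect_identical(sum(out$snps$is_spacer), 5L)
  expect_identical(nrow(out$snps), 11L)
  # relative order and count of real SNPs preserved
  expect_identical(out$snps$id[!out$snps$is_spacer], g$snps$id)
  # no length-6 window of consecutive SNPs contains members of both blocks
  real_block <- findInterval(out$snps$pos - 1L, c(0, 400, 4900, 5300))
  for (a in 1:(nrow(out$snps) - 5)) {
    win <- a:(a + 5)
    win <- win[!out$snps$is_spacer[win]]
    expect_lte(length(unique(real_block[win])), 1)
  }
  # positions remain strictly increasing
  expect_true(all(diff(out$snps$pos) > 0))
})

test_that("spacer insertion degenerate cases behave as documented", {
  coh <- small_cohort()
  g <- coh$genotypes
  one_block <- tibble::tibble(chrom = unique(g$snps$chrom),
                              start = 0L, end = 10000000L)
  expect_identical(insert_block_spacers(g, one_block, 6)$snps, g$snps)
  # empty map: default no insertion
  expect_identical(insert_block_spacers(g, NULL, 6)$snps, g$snps)
  # strict: every SNP isolated
  strict <- insert_block_spacers(g, NULL, max_window = 3, strict = TRUE)
  expect_identical(sum(strict$snps$is_spacer),
                   2L * (sum(table(g$snps$chrom) - 1L)))
})

test_that("spacers are exempt from filtering and never pruned", {
  coh <- small_cohort()
  g <- insert_block_spacers(coh$genotypes, coh$ld_blocks, max_window = 4)
  flt <- suppressMessages(filter_snps(g, 0.01, 0.9))
  expect_identical(sum(flt$snps$is_spacer), sum(g$snps$is_spacer))
  prn <- suppressMessages(prune_adjacent_ld(g, 0.5))
  expect_identical(sum(prn$snps$is_spacer), sum(g$snps$is_spacer))
})
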