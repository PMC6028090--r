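test_that("the same seed reproduces the cohort exactly", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_blocks = 5,
                    snps_per_block = 6, n_chroms = 2, risk_model = "dominant",
                    seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  # a different seed gives different data
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_cohort(cfg2)$genotypes$dosages,
                         a$genotypes$dosages))
})

test_that("cohort dimensions, quotas and layout match the config", {
  cfg <- sim_config(n_cases = 40, n_controls = 60, n_blocks = 6,
                    snps_per_block = 4, n_chroms = 3, seed = 7)
  coh <- generate_cohort(cfg)
  expect_identical(dim(coh$genotypes$dosages), c(100L, 24L))
  expect_identical(sum(coh$phenotypes$status), 40L)
  expect_identical(length(unique(coh$genotypes$snps$chrom)), 3L)
  expect_identical(nrow(coh$ld_blocks), 6L)
  # block intervals cover their SNPs
  for (b in seq_len(6)) {
    blk <- coh$ld_blocks[b, ]
    ids <- coh$genotypes$snps$chrom == blk$chrom &
      coh$genotypes$snps$pos - 1L >= blk$start &
      coh$genotypes$snps$pos - 1L < blk$end
    expect_identical(sum(ids), 4L)
  }
})

test_that("realized MAF tracks the haplotype-pool target at n >= 1000", {
  cfg <- sim_config(n_blocks = 20, snps_per_block = 5, risk_model = "null",
                    missing_rate = 0, seed = 11)
  coh <- generate_cohort(cfg)
  realized <- colMeans(coh$genotypes$dosages) / 2
  expect_identical(length(coh$truth$snp_target_maf), 100L)
  expect_lt(max(abs(realized - coh$truth$snp_target_maf)), 0.05)
})

test_that("blocks are independent while within-block LD is present", {
  cfg <- sim_config(n_blocks = 10, snps_per_block = 10, risk_model = "null",
                    missing_rate = 0, seed = 13)
  coh <- generate_cohort(cfg)
  d <- coh$genotypes$dosages
  set.seed(13)
  # 100 random cross-block pairs: mean |r| small
  cross <- replicate(100, {
    b <- sample(10, 2)
    i <- (b[1] - 1) * 10 + sample(10, 1)
    j <- (b[2] - 1) * 10 + sample(10, 1)
    abs(suppressWarnings(cor(d[, i], d[, j])))
  })
  expect_lt(mean(cross, na.rm = TRUE), 0.05)
  # within-block neighbor pairs show appreciable LD on average
  within <- sapply(0:9 * 10 + 1, function(i) {
    abs(suppressWarnings(cor(d[, i], d[, i + 1])))
  })
  expect_gt(mean(within, na.rm = TRUE), 0.1)
})

test_that("the truth record recomputes carrier status exactly", {
  for (model in c("dominant", "recessive", "compound_het",
                  "cis_epistatic_and")) {
    cfg <- sim_config(n_cases = 50, n_controls = 50, n_blocks = 4,
                      snps_per_block = 6, missing_rate = 0, n_chroms = 2,
                      risk_model = model, seed = 17)
    coh <- generate_cohort(cfg)
    carriers <- truth_carriers(coh$truth, coh$genotypes)
    d <- coh$genotypes$dosages[, coh$truth$target_snps, drop = FALSE]
    manual <- switch(model,
      dominant = d[, 1] >= 1,
      recessive = d[, 1] == 2,
      compound_het = d[, 1] >= 1 & d[, 2] >= 1,
      cis_epistatic_and = d[, 1] >= 1 & d[, 2] <= 1)
    expect_identical(carriers, unname(manual))
    expect_identical(coh$truth$risk_model, model)
  }
})

test_that("carriers are enriched among cases under a penetrant model", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_blocks = 4,
                    snps_per_block = 6, risk_model = "compound_het",
                    missing_rate = 0, n_chroms = 2,
                    penetrance_carrier = 0.5, penetrance_noncarrier = 0.1,
                    seed = 19)
  coh <- generate_cohort(cfg)
  carriers <- truth_carriers(coh$truth, coh$genotypes)
  rate_cases <- mean(carriers[coh$phenotypes$status == 1])
  rate_ctrl <- mean(carriers[coh$phenotypes$status == 0])
  expect_gt(rate_cases, rate_ctrl + 0.1)
})

test_that("unattainable quotas and invalid configs error out", {
  expect_error(sim_config(risk_model = "compound_het", targets = c(1L),
                          seed = 1), "2 targets")
  expect_error(sim_config(risk_model = "dominant", targets = c(99L),
                          seed = 1), "inside one block")
  expect_error(sim_config(seed = 1, frobnicate = 2), "unused argument")
  expect_error(sim_config(), "mandatory")
})

test_that("power_study summarizes rejection at a fixed rule", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_blocks = 4,
                    snps_per_block = 5, n_chroms = 2, risk_model = "null",
                    seed = 23)
  tab <- power_study(cfg, analyses = "ss", n_reps = 2,
                     alpha_rule = list(type = "fixed", s = -log10(0.05)),
                     qc = FALSE)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$seed, c(23L, 24L))
  expect_true(all(tab$rejection_rate >= 0 & tab$rejection_rate <= 1))
  expect_true(all(is.na(tab$locus_rank)))
})
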