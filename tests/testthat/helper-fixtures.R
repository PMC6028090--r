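# small deterministic fixtures built in code

# a genotype matrix from a plain dosage matrix (one chromosome)
toy_genotypes <- function(d, chrom = "1") {
  d <- as.matrix(d)
  genotype_matrix(
    d,
    tibble::tibble(chrom = chrom, pos = seq_len(ncol(d)) * 100L,
                   id = sprintf("snp%02d", seq_len(ncol(d))))
  )
}

# a random valid ordering matrix: antisymmetric with EQ diagonal
random_ordering <- function(n) {
  w <- matrix(NA_integer_, n, n)
  vals <- sample(c(-1L, 0L, 1L, NA), n * (n - 1) / 2, replace = TRUE)
  w[upper.tri(w)] <- vals
  tw <- t(w)
  w[lower.tri(w)] <- -tw[lower.tri(tw)]
  diag(w) <- 0L
  structure(w, class = "ordering_matrix")
}

# exact permutation p-value by full enumeration (independent of score_test)
exact_perm_p <- function(u, m) {
  n <- length(u)
  combos <- utils::combn(n, m)
  t_obs_all <- colSums(matrix(u[combos], nrow = m))
  function(t_obs) mean(abs(t_obs_all) >= abs(t_obs) - 1e-9)
}

# small cohort for scan tests
small_cohort <- function(seed = 42, risk_model = "null", ...) {
  cfg <- sim_config(n_cases = 25L, n_controls = 25L, n_blocks = 4L,
                    snps_per_block = 5L, haplotypes_per_block = 6L,
                    n_chroms = 2L, risk_model = risk_model,
                    missing_rate = 0.04, seed = seed, ...)
  generate_cohort(cfg)
}

ordering_matrix_all_eq <- function(n) {
  structure(matrix(0L, n, n), class = "ordering_matrix")
}

expect_ordering_valid <- function(w) {
  expect_true(all(diag(w) == 0L))
  na_w <- is.na(w)
  expect_true(all(na_w == t(na_w)))
  expect_true(all(w[!na_w] == -t(w)[!na_w]))
}
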