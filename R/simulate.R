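#' Specify a synthetic case/control cohort
#'
#' The generator emulates the structure the association scan is designed
#' for: biallelic SNPs organized in LD blocks, a roughly balanced
#' case/control split, a realistic MAF spectrum, and implanted risk loci
#' that are monotonic (additive/dominant/recessive) or cis-epistatic
#' (two interacting SNPs within one block).
#'
#' Haplotypes follow a star genealogy: per block, an all-major ancestral
#' haplotype is mutated independently at each SNP in `round(maf * H)` of
#' the `H = haplotypes_per_block` pool members; each subject draws two pool
#' haplotypes per block (uniformly, with replacement, independently across
#' blocks), so SNPs within a block are in LD (stronger for smaller pools)
#' and blocks are independent.
#'
#' Risk models act on carrier status at the target SNP(s) with penetrances
#' `penetrance_carrier` = P(case | carrier) and `penetrance_noncarrier` =
#' P(case | non-carrier):
#' * `null` — no associated SNP.
#' * `dominant` — carrier iff dosage >= 1; `recessive` — dosage == 2;
#'   `additive` — P(case) interpolates linearly in dosage/2.
#' * `cis_epistatic_and` — carrier iff minor allele present at target A AND
#'   major allele present at target B (dosage_A >= 1 and dosage_B <= 1).
#' * `compound_het` — carrier iff a minor allele is present at both targets
#'   (dosage >= 1 at both); the unphased proxy for disabling both copies.
#'
#' @param n_cases,n_controls subject counts (default 500/500).
#' @param n_blocks,snps_per_block panel layout (default 100 x 10 = 1,000
#'   SNPs).
#' @param haplotypes_per_block haplotype pool size H (default 12; LD blocks
#'   in real data typically carry on the order of a dozen common
#'   haplotypes).
#' @param maf_range target minor-allele frequency range, drawn uniformly
#'   (default `c(0.05, 0.5)`).
#' @param n_chroms chromosomes the blocks are dealt onto (default 10).
#' @param risk_model one of `"null"`, `"additive"`, `"dominant"`,
#'   `"recessive"`, `"cis_epistatic_and"`, `"compound_het"`.
#' @param targets integer vector of within-block SNP offsets for the target
#'   SNP(s) in the target block (defaults: SNP 4, and SNP 6 for two-SNP
#'   models, of the middle block).
#' @param target_block block index carrying the risk locus (default: middle
#'   block).
#' @param penetrance_carrier,penetrance_noncarrier P(case | carrier status)
#'   (defaults 0.3 / 0.1).
#' @param missing_rate uniform missing-call rate (default 0.005, typical of
#'   post-QC chip data).
#' @param seed integer seed; mandatory, every draw is derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cases = 500L, n_controls = 500L, n_blocks = 100L,
                       snps_per_block = 10L, haplotypes_per_block = 12L,
                       maf_range = c(0.05, 0.5), n_chroms = 10L,
                       risk_model = c("null", "additive", "dominant",
                                      "recessive", "cis_epistatic_and",
                                      "compound_het"),
                       targets = NULL, target_block = NULL,
                       penetrance_carrier = 0.3,
                       penetrance_noncarrier = 0.1,
                       missing_rate = 0.005, seed) {
  risk_model <- match.arg(risk_model)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_cases > 0, n_controls > 0, n_blocks > 0, snps_per_block > 0,
            haplotypes_per_block >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            penetrance_carrier > 0, penetrance_carrier < 1,
            penetrance_noncarrier > 0, penetrance_noncarrier < 1,
            missing_rate >= 0, missing_rate < 1)
  two_snp <- risk_model %in% c("cis_epistatic_and", "compound_het")
  if (is.null(target_block)) target_block <- max(1L, n_blocks %/% 2L)
  if (is.null(targets)) {
    targets <- if (two_snp) c(4L, 6L) else 4L
    targets <- pmin(targets, snps_per_block)
    if (two_snp && targets[1] == targets[2]) targets <- c(1L, 2L)
  }
  if (risk_model != "null") {
    if (two_snp && length(targets) != 2L) {
      stop("two-SNP risk models need exactly 2 targets", call. = FALSE)
    }
    if (!two_snp && length(targets) != 1L) {
      stop("single-SNP risk models need exactly 1 target", call. = FALSE)
    }
    if (any(targets < 1L | targets > snps_per_block)) {
      stop("targets must lie inside one block", call. = FALSE)
    }
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_blocks = as.integer(n_blocks),
         snps_per_block = as.integer(snps_per_block),
         haplotypes_per_block = as.integer(haplotypes_per_block),
         maf_range = as.numeric(maf_range), n_chroms = as.integer(n_chroms),
         risk_model = risk_model, targets = as.integer(targets),
         target_block = as.integer(target_block),
         penetrance_carrier = penetrance_carrier,
         penetrance_noncarrier = penetrance_noncarrier,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

carrier_status <- function(cfg, target_dosages) {
  d <- target_dosages
  switch(cfg$risk_model,
    null = rep(FALSE, nrow(d)),
    dominant = !is.na(d[, 1]) & d[, 1] >= 1L,
    recessive = !is.na(d[, 1]) & d[, 1] == 2L,
    additive = !is.na(d[, 1]) & d[, 1] >= 1L,  # carrier used for bookkeeping
    cis_epistatic_and = !is.na(d[, 1]) & !is.na(d[, 2]) &
      d[, 1] >= 1L & d[, 2] <= 1L,
    compound_het = !is.na(d[, 1]) & !is.na(d[, 2]) &
      d[, 1] >= 1L & d[, 2] >= 1L
  )
}

case_probability <- function(cfg, target_dosages) {
  if (cfg$risk_model == "null") {
    # overall prevalence is irrelevant under quota sampling; use the mean
    return(rep(mean(c(cfg$penetrance_carrier, cfg$penetrance_noncarrier)),
               nrow(target_dosages)))
  }
  if (cfg$risk_model == "additive") {
    d <- target_dosages[, 1]
    d[is.na(d)] <- 0L
    return(cfg$penetrance_noncarrier +
             (cfg$penetrance_carrier - cfg$penetrance_noncarrier) * d / 2)
  }
  ifelse(carrier_status(cfg, target_dosages),
         cfg$penetrance_carrier, cfg$penetrance_noncarrier)
}

#' Generate a synthetic case/control cohort
#'
#' Subjects are simulated in batches and assigned case/control status by the
#' risk model's penetrances until the exact `n_cases` / `n_controls` quotas
#' are filled (bounded resampling; an unattainable quota errors out).
#' Missing calls are then applied uniformly at random. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` ([genotype_matrix()]), `phenotypes`
#'   (tibble), `ld_blocks` (BED-style tibble of block intervals), and
#'   `truth` (target SNP ids, risk model, penetrances — enough to recompute
#'   carrier status exactly).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  p <- cfg$n_blocks * cfg$snps_per_block
  hh <- cfg$haplotypes_per_block

  # layout: blocks dealt contiguously onto chromosomes, 1 kb SNP spacing,
  # 50 kb between blocks
  block_chrom <- sort(rep_len(seq_len(cfg$n_chroms), cfg$n_blocks))
  snp_meta <- vector("list", cfg$n_blocks)
  ld_blocks <- vector("list", cfg$n_blocks)
  pools <- vector("list", cfg$n_blocks)
  target_maf <- numeric(p)
  pos_cursor <- stats::setNames(rep(1L, cfg$n_chroms),
                                as.character(seq_len(cfg$n_chroms)))
  for (b in seq_len(cfg$n_blocks)) {
    ch <- as.character(block_chrom[b])
    maf <- stats::runif(cfg$snps_per_block, cfg$maf_range[1],
                        cfg$maf_range[2])
    pool <- matrix(0L, hh, cfg$snps_per_block)
    for (j in seq_len(cfg$snps_per_block)) {
      n_carrier <- max(1L, min(hh - 1L, round(maf[j] * hh)))
      pool[sample.int(hh, n_carrier), j] <- 1L
    }
    pools[[b]] <- pool
    start <- pos_cursor[ch]
    pos <- start + (seq_len(cfg$snps_per_block) - 1L) * 1000L
    pos_cursor[ch] <- pos[length(pos)] + 50000L
    snp_meta[[b]] <- tibble::tibble(
      chrom = ch, pos = as.integer(pos),
      id = sprintf("b%03d_s%02d", b, seq_len(cfg$snps_per_block))
    )
    ld_blocks[[b]] <- tibble::tibble(
      chrom = ch, start = as.integer(pos[1] - 1L),
      end = as.integer(pos[length(pos)]),
      name = sprintf("block_%03d", b)
    )
    target_maf[(b - 1L) * cfg$snps_per_block + seq_len(cfg$snps_per_block)] <-
      colMeans(pool)
  }
  snps <- dplyr::bind_rows(snp_meta)

  target_cols <- if (cfg$risk_model == "null") integer(0) else
    (cfg$target_block - 1L) * cfg$snps_per_block + cfg$targets

  draw_batch <- function(nb) {
    d <- matrix(0L, nb, p)
    for (b in seq_len(cfg$n_blocks)) {
      h1 <- sample.int(hh, nb, replace = TRUE)
      h2 <- sample.int(hh, nb, replace = TRUE)
      cols <- (b - 1L) * cfg$snps_per_block + seq_len(cfg$snps_per_block)
      d[, cols] <- pools[[b]][h1, , drop = FALSE] +
        pools[[b]][h2, , drop = FALSE]
    }
    d
  }

  n_target <- cfg$n_cases + cfg$n_controls
  case_rows <- list(); control_rows <- list()
  n_case_have <- 0L; n_control_have <- 0L
  attempts <- 0L
  while (n_case_have < cfg$n_cases || n_control_have < cfg$n_controls) {
    attempts <- attempts + 1L
    if (attempts > 60L) {
      stop("case/control quota unattainable after bounded resampling ",
           "(penetrances too extreme for the requested split)",
           call. = FALSE)
    }
    d <- draw_batch(n_target)
    pr <- if (length(target_cols)) {
      case_probability(cfg, d[, target_cols, drop = FALSE])
    } else {
      case_probability(cfg, matrix(0L, nrow(d), 1))
    }
    is_case <- stats::runif(nrow(d)) < pr
    need_case <- cfg$n_cases - n_case_have
    need_control <- cfg$n_controls - n_control_have
    if (need_case > 0L && any(is_case)) {
      take <- utils::head(which(is_case), need_case)
      case_rows[[length(case_rows) + 1L]] <- d[take, , drop = FALSE]
      n_case_have <- n_case_have + length(take)
    }
    if (need_control > 0L && any(!is_case)) {
      take <- utils::head(which(!is_case), need_control)
      control_rows[[length(control_rows) + 1L]] <- d[take, , drop = FALSE]
      n_control_have <- n_control_have + length(take)
    }
  }
  d <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  status <- rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls))
  shuffle <- sample.int(nrow(d))
  d <- d[shuffle, , drop = FALSE]
  status <- status[shuffle]

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(d)) < cfg$missing_rate
    d[mask] <- NA_integer_
  }
  subjects <- sprintf("S%05d", seq_len(nrow(d)))
  g <- genotype_matrix(d, snps, subjects)

  truth <- list(
    risk_model = cfg$risk_model,
    target_snps = if (length(target_cols)) snps$id[target_cols] else
      character(0),
    target_block = if (cfg$risk_model == "null") NA_integer_ else
      cfg$target_block,
    penetrance_carrier = cfg$penetrance_carrier,
    penetrance_noncarrier = cfg$penetrance_noncarrier,
    target_maf = if (length(target_cols)) target_maf[target_cols] else
      numeric(0),
    snp_target_maf = target_maf,  # pool minor-allele frequency, every SNP
    seed = cfg$seed
  )
  list(genotypes = g,
       phenotypes = phenotype_table(subjects, status),
       ld_blocks = dplyr::bind_rows(ld_blocks),
       truth = truth)
}

#' Recompute carrier status from a truth record
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param g the cohort's [genotype_matrix()].
#' @return logical vector per subject.
#' @export
truth_carriers <- function(truth, g) {
  if (truth$risk_model == "null") return(rep(FALSE, n_subjects(g)))
  cols <- match(truth$target_snps, g$snps$id)
  cfg_like <- list(risk_model = truth$risk_model)
  unname(carrier_status(cfg_like, g$dosages[, cols, drop = FALSE]))
}

#' Type-I error / power harness
#'
#' Runs repeated simulated cohorts through the single-SNP and/or windowed
#' analyses and summarizes, per configuration cell: the rejection rate at
#' the chosen significance rule, and (for non-null models) the median rank
#' and median s-value of the implanted locus. Rep r of a cell uses seed
#' `cfg$seed + r - 1`; all seeds are recorded in the output.
#'
#' @param configs a [sim_config()] or list of them.
#' @param analyses subset of `c("ss", "mu")`.
#' @param n_reps replicates per cell (>= 1; the harness is routinely run
#'   with 20+).
#' @param alpha_rule either `list(type = "fixed", s = <cutoff>)` — a fixed
#'   per-test s threshold, e.g. `-log10(0.05)` for nominal typing or 7.3
#'   for classical GWS — or `list(type = "agws")` to use each cohort's own
#'   adaptive cutoff.
#' @param max_window passed to [mu_gwas()].
#' @param qc apply [filter_snps()] + [insert_block_spacers()] before
#'   analysis (default TRUE).
#' @return tibble: one row per cell x analysis x rep with `rejection_rate`
#'   (fraction of centers above the rule), `locus_rank`, `locus_s`, `seed`,
#'   `cutoff`.
#' @export
power_study <- function(configs, analyses = c("ss", "mu"), n_reps = 20L,
                        alpha_rule = list(type = "fixed", s = 7.3),
                        max_window = 6L, qc = TRUE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  analyses <- match.arg(analyses, c("ss", "mu"), several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg0 <- configs[[ci]]
    for (r in seq_len(n_reps)) {
      cfg <- cfg0
      cfg$seed <- cfg0$seed + r - 1L
      cohort <- generate_cohort(cfg)
      g <- cohort$genotypes
      if (qc) {
        g <- suppressMessages(filter_snps(g))
        g <- insert_block_spacers(g, cohort$ld_blocks,
                                  max_window = max_window)
      }
      for (an in analyses) {
        res <- if (an == "ss") single_snp_gwas(g, cohort$phenotypes) else
          mu_gwas(g, cohort$phenotypes, max_window = max_window)
        cutoff <- if (alpha_rule$type == "fixed") alpha_rule$s else
          agws_cutoff(res)$agws
        locus <- match(cohort$truth$target_snps, res$snp_id)
        locus <- locus[!is.na(locus)]
        locus_s <- if (length(locus)) max(res$s[locus]) else NA_real_
        locus_rank <- if (length(locus)) {
          min(rank(-res$s, ties.method = "min")[locus])
        } else NA_real_
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell = ci, rep = r, seed = cfg$seed, analysis = an,
          risk_model = cfg$risk_model, n_centers = nrow(res),
          cutoff = cutoff,
          rejection_rate = mean(res$s > cutoff),
          locus_rank = locus_rank, locus_s = locus_s
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
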