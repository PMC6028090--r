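#' Subject u-scores from an ordering matrix
#'
#' Each subject's score is the number of subjects carrying lower risk minus
#' the number carrying higher risk, oriented so that a higher score means
#' higher risk. Antisymmetry of the ordering matrix forces the scores to sum
#' to zero.
#'
#' @param w an `ordering_matrix`.
#' @return integer vector of per-subject scores.
#' @examples
#' u_scores(snp_ordering(c(0, 1, 2), +1))  # -2 0 2
#' @export
u_scores <- function(w) {
  as.integer(rowSums(unclass(w), na.rm = TRUE))
}

#' Linear score test of u-scores against case/control status
#'
#' Tests whether cases carry systematically higher u-scores than controls.
#' The statistic is T = sum of case scores; under the permutation null of
#' drawing the m cases from the n subjects without replacement, E(T) = 0 and
#' Var(T) = m(n-m) / (n(n-1)) * sum(u^2). `method = "normal"` refers
#' Z = T/sqrt(Var) to the standard normal (two-sided); `method = "exact"`
#' enumerates all case/control relabelings (n <= 20) and reports
#' P(|T*| >= |T|).
#'
#' @param u integer u-score vector.
#' @param status 0/1 vector (1 = case), same length and order as `u`.
#' @param method `"normal"` (default) or `"exact"`.
#' @return one-row tibble: `t`, `var_t`, `statistic` (Z), `p`, `s`
#'   (`-log10(p)`), `non_informative`.
#' @export
score_test <- function(u, status, method = c("normal", "exact")) {
  method <- match.arg(method)
  status <- as.integer(status)
  stopifnot(length(u) == length(status), all(status %in% 0:1))
  n <- length(u)
  m <- sum(status)
  if (m == 0L || m == n) stop("need both cases and controls", call. = FALSE)
  sum_u2 <- sum(as.numeric(u)^2)
  t_stat <- sum(u[status == 1L])
  if (sum_u2 == 0) {
    return(tibble::tibble(t = 0, var_t = 0, statistic = 0, p = 1, s = 0,
                          non_informative = TRUE))
  }
  var_t <- m * (n - m) / (n * (n - 1)) * sum_u2
  z <- t_stat / sqrt(var_t)
  if (method == "normal") {
    p <- 2 * stats::pnorm(-abs(z))
    p <- max(p, .Machine$double.xmin)
  } else {
    if (n > 20L) stop("exact method enforced for n <= 20", call. = FALSE)
    combos <- utils::combn(n, m)
    t_all <- colSums(matrix(u[combos], nrow = m))
    p <- mean(abs(t_all) >= abs(t_stat) - 1e-9)
  }
  tibble::tibble(t = t_stat, var_t = var_t, statistic = z, p = p,
                 s = -log10(p), non_informative = FALSE)
}

#' Single-SNP GWAS with the univariate u-test
#'
#' The traditional per-SNP scan: each SNP's monotonic ordering (minor-allele
#' polarity +1; the sign only flips Z and leaves the two-sided p unchanged)
#' is converted to u-scores and tested with the linear score test. Fully
#' vectorized across SNPs via the dosage-class counts.
#'
#' @param g a QC'd [genotype_matrix()].
#' @param phenotype a phenotype table (`subject_id`, `status`) or 0/1 vector
#'   in subject order.
#' @return tibble, one row per non-spacer SNP: `chrom`, `pos`, `snp_id`,
#'   `analysis` (`"ss"`), `window_snps`, `polarity`, `ic`, `z`, `p`, `s`,
#'   `flags`.
#' @export
single_snp_gwas <- function(g, phenotype) {
  status <- align_status(g, phenotype)
  keep <- !g$snps$is_spacer
  d <- g$dosages[, keep, drop = FALSE]
  n <- nrow(d)
  m <- sum(status)

  cnt <- function(val, rows) {
    colSums(!is.na(d[rows, , drop = FALSE]) & d[rows, , drop = FALSE] == val)
  }
  all_rows <- seq_len(n)
  cases <- which(status == 1L)
  n0 <- cnt(0L, all_rows); n1 <- cnt(1L, all_rows); n2 <- cnt(2L, all_rows)
  m0 <- cnt(0L, cases); m1 <- cnt(1L, cases); m2 <- cnt(2L, cases)
  n_obs <- n0 + n1 + n2

  # per dosage-class u-score: #(lower) - #(higher) among observed subjects
  u0 <- -(n1 + n2); u1 <- n0 - n2; u2 <- n0 + n1
  t_stat <- m0 * u0 + m1 * u1 + m2 * u2
  sum_u2 <- n0 * u0^2 + n1 * u1^2 + n2 * u2^2
  var_t <- m * (n - m) / (n * (n - 1)) * sum_u2
  z <- ifelse(var_t > 0, t_stat / sqrt(var_t), 0)
  p <- ifelse(var_t > 0, pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), 1)
  ic <- n_obs * (n_obs - 1) / (n * (n - 1))

  tibble::tibble(
    chrom = g$snps$chrom[keep],
    pos = g$snps$pos[keep],
    snp_id = g$snps$id[keep],
    analysis = "ss",
    window_snps = g$snps$id[keep],
    polarity = "1",
    ic = unname(ic),
    z = unname(as.numeric(z)),
    p = unname(as.numeric(p)),
    s = unname(-log10(p)),
    flags = unname(ifelse(var_t <= 0, "non_informative",
                          ifelse(p <= .Machine$double.xmin, "p_floored", "")))
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Enumerate diplotype candidates for one center SNP
#'
#' All contiguous windows of length 1..`max_window` containing the center
#' (clipped at chromosome ends and never crossing spacer SNPs) are crossed
#' with all polarity assignments over `{-1, 0, +1}` (the all-zero vector and
#' global sign-flip duplicates, which transpose W without changing |Z|, p or
#' IC, are skipped). Each candidate is scored with the windowed u-test.
#'
#' @param g a QC'd, spacer-inserted [genotype_matrix()].
#' @param phenotype phenotype table or 0/1 status vector.
#' @param center column index of the (non-spacer) center SNP.
#' @param max_window maximum window length (default 6).
#' @param ic_min candidates with information content below this are dropped
#'   (default 0 keeps all).
#' @return tibble of candidates: window bounds, polarity string, `ic`, `z`,
#'   `p`, `s`, `non_informative`.
#' @export
candidate_scan <- function(g, phenotype, center, max_window = 6L,
                           ic_min = 0) {
  status <- align_status(g, phenotype)
  if (g$snps$is_spacer[center]) stop("center is a spacer SNP", call. = FALSE)
  res <- cpp_scan_centers(
    g$dosages, snp_runs(g)$start, snp_runs(g)$end,
    as.integer(center), as.integer(status),
    as.integer(max_window), as.numeric(ic_min), TRUE
  )
  decode_candidates(res, g)
}

#' Select the best candidate by the (-log10 p, IC) dominance criterion
#'
#' Each candidate is ranked by a bivariate dominance u-score: the number of
#' candidates it weakly dominates (lower-or-equal on both significance and
#' information content, strictly on one) minus the number that weakly
#' dominate it. The argmax avoids over-fitting: a candidate that gains
#' significance only by sacrificing decidable pairs does not dominate.
#' Ties are broken by higher IC, then shorter window, then lexicographically
#' smallest polarity; the choice is invariant to the order of the list.
#'
#' @param candidates tibble from [candidate_scan()].
#' @return the selected row, with `dominance` attached.
#' @export
select_best <- function(candidates) {
  if (nrow(candidates) == 0L) stop("no candidates", call. = FALSE)
  sc <- dominance_scores(candidates$s, candidates$ic)
  col_or <- function(name, default) {
    if (name %in% names(candidates)) candidates[[name]] else
      rep(default, nrow(candidates))
  }
  ord <- order(-sc, -candidates$ic,
               col_or("win_len", 0L), col_or("pol_key", 0),
               col_or("win_start", 0L))
  out <- candidates[ord[1L], , drop = FALSE]
  out$dominance <- sc[ord[1L]]
  out
}

# score(c) = #{d weakly below-left of c} - #{d weakly above-right}
# (counts including c itself cancel in the difference)
dominance_scores <- function(s, ic) {
  k <- length(s)
  le <- ge <- integer(k)
  for (i in seq_len(k)) {
    le[i] <- sum(s <= s[i] & ic <= ic[i])
    ge[i] <- sum(s >= s[i] & ic >= ic[i])
  }
  le - ge
}

#' Genetically structured multivariate GWAS over sliding SNP windows
#'
#' For every non-spacer SNP, enumerates all diplotype windows centered at it
#' with all polarity assignments, scores each with the windowed u-test, and
#' keeps the candidate with the highest (-log10 p, IC) dominance score. The
#' scan collapses subjects with identical window genotype profiles, so the
#' cost per candidate scales with the number of distinct profiles, not with
#' n^2.
#'
#' @inheritParams candidate_scan
#' @param max_window maximum diplotype length (default 6).
#' @return tibble, one row per non-spacer SNP, columns as
#'   [single_snp_gwas()] plus `dominance` and `n_candidates`; sorted by
#'   `(chrom, pos)`.
#' @export
mu_gwas <- function(g, phenotype, max_window = 6L, ic_min = 0) {
  status <- align_status(g, phenotype)
  centers <- which(!g$snps$is_spacer)
  runs <- snp_runs(g)
  res <- cpp_scan_centers(
    g$dosages, runs$start, runs$end,
    as.integer(centers), as.integer(status),
    as.integer(max_window), as.numeric(ic_min), FALSE
  )
  decode_candidates(res, g, best = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

# Contiguous runs of non-spacer SNPs within a chromosome: for each column,
# the first and last column index of its run (spacers get their own index).
# Windows are enumerated inside these runs only.
snp_runs <- function(g) {
  p <- n_snps(g)
  chrom_f <- as.integer(factor(g$snps$chrom, unique(g$snps$chrom)))
  brk <- g$snps$is_spacer | c(TRUE, diff(chrom_f) != 0L)
  run_id <- cumsum(brk | c(FALSE, g$snps$is_spacer[-p]))
  start <- stats::ave(seq_len(p), run_id, FUN = min)
  end <- stats::ave(seq_len(p), run_id, FUN = max)
  list(start = as.integer(start), end = as.integer(end))
}

# Turn the numeric matrix returned by cpp_scan_centers into a results tibble.
decode_candidates <- function(res, g, best = FALSE) {
  res <- as.data.frame(res)
  names(res) <- c("center", "win_start", "win_len", "pol_code", "ic", "z",
                  "p", "s", "non_informative", "n_candidates", "dominance")
  center <- as.integer(res$center)
  win_start <- as.integer(res$win_start)
  win_len <- as.integer(res$win_len)
  pol <- vapply(seq_len(nrow(res)), function(i) {
    paste(decode_polarity(res$pol_code[i], win_len[i]), collapse = ",")
  }, character(1))
  win_ids <- vapply(seq_len(nrow(res)), function(i) {
    paste(g$snps$id[win_start[i]:(win_start[i] + win_len[i] - 1L)],
          collapse = ",")
  }, character(1))
  out <- tibble::tibble(
    chrom = g$snps$chrom[center],
    pos = g$snps$pos[center],
    snp_id = g$snps$id[center],
    analysis = "mu",
    window_snps = win_ids,
    polarity = pol,
    win_start = win_start,
    win_len = win_len,
    # numeric lexicographic key over the polarity digits (first SNP most
    # significant); used only for deterministic tie-breaking
    pol_key = vapply(seq_len(nrow(res)), function(i) {
      d <- decode_polarity(res$pol_code[i], win_len[i]) + 1L
      sum(d * 3^rev(seq_along(d) - 1L))
    }, numeric(1)),
    ic = res$ic,
    z = res$z,
    p = res$p,
    s = res$s,
    flags = ifelse(res$non_informative > 0, "non_informative",
                   ifelse(res$p <= .Machine$double.xmin, "p_floored", ""))
  )
  if (best) {
    out$dominance <- as.integer(res$dominance)
    out$n_candidates <- as.integer(res$n_candidates)
  }
  out
}

# base-3 polarity code -> vector over {-1,0,+1}; digit order = window order
decode_polarity <- function(code, len) {
  digits <- integer(len)
  for (j in seq_len(len)) {
    digits[j] <- code %% 3
    code <- code %/% 3
  }
  digits - 1L
}
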