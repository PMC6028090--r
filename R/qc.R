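#' Exclude non-informative and low-quality SNPs
#'
#' Removes SNPs with sample minor-allele frequency below `maf_min` or call
#' rate below `callrate_min`. Spacer SNPs are exempt. Removal counts are
#' reported via `message()` and attached as the `"qc_log"` attribute.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum sample MAF (default 0.01).
#' @param callrate_min minimum fraction of non-missing calls (default 0.9).
#' @return the filtered [genotype_matrix()].
#' @export
filter_snps <- function(g, maf_min = 0.01, callrate_min = 0.9) {
  stopifnot(maf_min >= 0, maf_min < 0.5, callrate_min > 0, callrate_min <= 1)
  d <- g$dosages
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  callrate <- colMeans(!is.na(d))
  low_maf <- !g$snps$is_spacer & (is.na(maf) | maf < maf_min)
  low_call <- !g$snps$is_spacer & !low_maf & callrate < callrate_min
  keep <- g$snps$is_spacer | !(low_maf | low_call)
  if (!any(keep & !g$snps$is_spacer)) {
    stop("no informative SNPs after filtering", call. = FALSE)
  }
  message("filter_snps: removed ", sum(low_maf), " SNP(s) with MAF < ",
          maf_min, " and ", sum(low_call), " with call rate < ", callrate_min)
  out <- subset_snps(g, keep)
  attr(out, "qc_log") <- c(attr(g, "qc_log"),
                           sprintf("filter_snps: maf_min=%g callrate_min=%g removed_maf=%d removed_callrate=%d",
                                   maf_min, callrate_min, sum(low_maf),
                                   sum(low_call)))
  out
}

#' Prune SNPs in high LD with their immediate neighbor
#'
#' Scans each chromosome left to right and drops any SNP whose squared
#' Pearson correlation of dosages (pairwise-complete) with the previously
#' retained SNP exceeds `r2_max`. Keeping only one tag per run of
#' near-duplicate neighbors avoids the power loss of carrying redundant
#' SNPs through the windowed scan. Spacer SNPs reset the scan (they mark
#' block boundaries) and are never dropped.
#'
#' @param g a [genotype_matrix()].
#' @param r2_max maximum allowed neighbor r-squared (default 0.95).
#' @return the pruned [genotype_matrix()]; proportion pruned is messaged and
#'   appended to the `"qc_log"` attribute.
#' @export
prune_adjacent_ld <- function(g, r2_max = 0.95) {
  stopifnot(r2_max > 0, r2_max <= 1)
  d <- g$dosages
  chrom <- g$snps$chrom
  drop <- logical(n_snps(g))
  prev <- NA_integer_
  prev_chrom <- NA_character_
  for (j in seq_len(n_snps(g))) {
    if (g$snps$is_spacer[j]) { prev <- NA_integer_; next }
    if (!identical(chrom[j], prev_chrom)) prev <- NA_integer_
    prev_chrom <- chrom[j]
    if (!is.na(prev)) {
      r <- suppressWarnings(
        stats::cor(d[, prev], d[, j], use = "pairwise.complete.obs")
      )
      if (!is.na(r) && r^2 > r2_max) { drop[j] <- TRUE; next }
    }
    prev <- j
  }
  n_informative <- sum(!g$snps$is_spacer)
  message("prune_adjacent_ld: dropped ", sum(drop), " of ", n_informative,
          " SNP(s) (", round(100 * sum(drop) / max(n_informative, 1), 1),
          "%) at r2 > ", r2_max)
  out <- subset_snps(g, !drop)
  attr(out, "qc_log") <- c(attr(g, "qc_log"),
                           sprintf("prune_adjacent_ld: r2_max=%g dropped=%d of %d",
                                   r2_max, sum(drop), n_informative))
  out
}

#' Insert non-informative spacer SNPs at LD-block boundaries
#'
#' Between consecutive LD blocks, `max_window - 1` all-missing spacer SNPs
#' are inserted so that no analysis window of length up to `max_window`
#' contains SNPs from two blocks. Spacers are never test centers. SNPs not
#' covered by any interval are treated as singleton blocks. With an empty
#' block map the default is to insert nothing; `strict = TRUE` instead
#' isolates every SNP (each its own block).
#'
#' @param g a [genotype_matrix()].
#' @param blocks tibble of BED-style intervals (`chrom`, `start`, `end`;
#'   0-based half-open), e.g. from [read_bed_intervals()]; may be `NULL` or
#'   empty.
#' @param max_window the maximum analysis window length the spacers must
#'   defeat (default 6).
#' @param strict with an empty/`NULL` block map, isolate every SNP.
#' @return a [genotype_matrix()] with spacers inserted.
#' @export
insert_block_spacers <- function(g, blocks, max_window = 6L,
                                 strict = FALSE) {
  k <- as.integer(max_window) - 1L
  empty_map <- is.null(blocks) || nrow(blocks) == 0L
  if (empty_map && !strict) return(g)
  if (k < 1L) return(g)

  # block id per SNP: matched interval, or a unique singleton id
  block_id <- character(n_snps(g))
  for (j in seq_len(n_snps(g))) {
    if (empty_map) { block_id[j] <- paste0(".single_", j); next }
    hit <- which(blocks$chrom == g$snps$chrom[j] &
                   blocks$start <= g$snps$pos[j] - 1L &
                   g$snps$pos[j] - 1L < blocks$end)
    block_id[j] <- if (length(hit)) paste0("b", hit[1]) else
      paste0(".single_", j)
  }

  pieces_d <- list()
  pieces_s <- list()
  spacer_n <- 0L
  boundary <- which(
    diff(as.integer(factor(block_id, unique(block_id)))) != 0 &
      g$snps$chrom[-1] == g$snps$chrom[-n_snps(g)]
  )
  prev_cut <- 0L
  for (b in c(boundary, n_snps(g))) {
    idx <- (prev_cut + 1L):b
    pieces_d[[length(pieces_d) + 1L]] <- g$dosages[, idx, drop = FALSE]
    pieces_s[[length(pieces_s) + 1L]] <- g$snps[idx, , drop = FALSE]
    if (b < n_snps(g) && b %in% boundary) {
      lo <- g$snps$pos[b]; hi <- g$snps$pos[b + 1L]
      if (hi - lo <= k) {
        stop("cannot place ", k, " spacers between positions ", lo, " and ",
             hi, " on ", g$snps$chrom[b],
             ": coordinate gap too small", call. = FALSE)
      }
      pos_sp <- lo + round(seq_len(k) * (hi - lo) / (k + 1))
      if (pos_sp[1] <= lo || pos_sp[k] >= hi || any(diff(pos_sp) <= 0)) {
        pos_sp <- lo + seq_len(k)   # narrow gap: pack against left flank
      }
      spacer_n <- spacer_n + k
      pieces_d[[length(pieces_d) + 1L]] <-
        matrix(NA_integer_, n_subjects(g), k)
      pieces_s[[length(pieces_s) + 1L]] <- tibble::tibble(
        chrom = g$snps$chrom[b],
        pos = as.integer(pos_sp),
        id = sprintf("spacer_%s_%d_%d", g$snps$chrom[b], b, seq_len(k)),
        is_spacer = TRUE
      )
    }
    prev_cut <- b
  }
  genotype_matrix(do.call(cbind, pieces_d), dplyr::bind_rows(pieces_s),
                  g$subjects)
}
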