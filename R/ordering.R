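#' Pairwise risk-ordering algebra
#'
#' An ordering matrix records, for every pair of subjects, whether the row
#' subject carries lower (`-1`), equal (`0`) or higher (`+1`) genetic risk
#' than the column subject, or whether the comparison is undecided (`NA`,
#' printed `?`). Single-SNP orderings treat the genotype as merely monotonic
#' in minor-allele count (aa < aA < AA), i.e. neither a recessive, additive
#' nor dominant scoring is imposed. Orderings from neighboring SNPs are
#' combined with the logical-AND operator [lambda2()]: agreement propagates,
#' conflict yields "undecided".
#'
#' @name ordering
NULL

ORD_LEVELS <- c(`-1` = "<", `0` = "=", `1` = ">")

#' Single-SNP subject ordering
#'
#' @param dosages integer vector of minor-allele dosages (`0,1,2,NA`).
#' @param polarity `+1` if the minor allele is treated as the risk allele,
#'   `-1` if protective (which transposes the matrix).
#' @return An n x n `ordering_matrix` with codes `-1` (row subject lower
#'   risk), `0` (equal), `+1` (higher), `NA` (undecided; any comparison
#'   involving a missing genotype). The diagonal is `0` by convention.
#' @examples
#' snp_ordering(c(0, 1, 2), +1)
#' @export
snp_ordering <- function(dosages, polarity = 1L) {
  stopifnot(polarity %in% c(-1L, 1L))
  d <- as.integer(dosages)
  w <- sign(outer(d, d, `-`)) * as.integer(polarity)
  diag(w) <- 0L
  ordering_matrix(w)
}

ordering_matrix <- function(w) {
  storage.mode(w) <- "integer"
  structure(w, class = "ordering_matrix")
}

#' @method print ordering_matrix
#' @export
print.ordering_matrix <- function(x, ...) {
  cat("<ordering_matrix> ", nrow(x), " subjects\n", sep = "")
  cat(format_ordering(x), sep = "\n")
  invisible(x)
}

#' Render an ordering matrix as a 4-symbol text grid
#'
#' Debug/golden-test helper: one row per subject, symbols `<`, `=`, `>`, `?`.
#' @param w an `ordering_matrix`.
#' @export
format_ordering <- function(w) {
  sym <- matrix("?", nrow(w), ncol(w))
  sym[!is.na(w)] <- ORD_LEVELS[as.character(w[!is.na(w)])]
  apply(sym, 1, paste, collapse = "")
}

#' Logical-AND of two pairwise orderings
#'
#' Combines the risk orderings contributed by two neighboring SNPs for the
#' same subject pair. A decided direction propagates through `=` and `?`;
#' opposite directions conflict and yield `?`. Vectorized: `a` and `b` may
#' be equal-shaped matrices.
#'
#' @param a,b ordering codes (`-1`, `0`, `1`, `NA`).
#' @return elementwise combination under the same coding.
#' @export
lambda2 <- function(a, b) {
  lambda_combine(list(a, b))
}

#' Logical-AND of several orderings (multiset rule)
#'
#' The permutation-invariant extension of [lambda2()]: undecided if both
#' directions are present, else the direction present, else `=` if present,
#' else undecided. Note that folding [lambda2()] sequentially is *not*
#' associative (a conflict can be masked by an interleaved `=`), so the
#' multiset rule is the definition used throughout.
#'
#' @param values vector of ordering codes (length >= 1).
#' @return a single ordering code.
#' @export
lambda_multi <- function(values) {
  stopifnot(length(values) >= 1)
  has_lt <- any(values == -1L, na.rm = TRUE)
  has_gt <- any(values == 1L, na.rm = TRUE)
  has_eq <- any(values == 0L, na.rm = TRUE)
  if (has_lt && has_gt) return(NA_integer_)
  if (has_lt) return(-1L)
  if (has_gt) return(1L)
  if (has_eq) return(0L)
  NA_integer_
}

# Elementwise multiset combination of a list of equal-shaped code arrays.
lambda_combine <- function(mats) {
  has_lt <- Reduce(`|`, lapply(mats, function(m) !is.na(m) & m == -1L))
  has_gt <- Reduce(`|`, lapply(mats, function(m) !is.na(m) & m == 1L))
  has_eq <- Reduce(`|`, lapply(mats, function(m) !is.na(m) & m == 0L))
  out <- array(NA_integer_, dim = dim2(mats[[1]]))
  out[has_lt & !has_gt] <- -1L
  out[has_gt & !has_lt] <- 1L
  out[!has_lt & !has_gt & has_eq] <- 0L
  if (is.null(dim(mats[[1]]))) out <- as.vector(out)
  out
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Diplotype ordering for a SNP window
#'
#' Aggregates a window of neighboring SNPs into one pairwise ordering
#' matrix W. SNPs with polarity 0 are dropped; a single retained SNP reduces
#' to [snp_ordering()]; otherwise the consecutive pairwise matrices
#' I(k, k+1) = lambda2(S_k, S_{k+1}) are formed and combined elementwise with
#' the multiset rule. Because the pairwise step precedes aggregation, the
#' same tag SNPs in a different arrangement can give a different W.
#'
#' @param g a [genotype_matrix()].
#' @param snp_indices contiguous ascending column indices of the window.
#' @param polarity integer vector over `{-1, 0, +1}`, one per window SNP,
#'   not all zero.
#' @return an `ordering_matrix` over the subjects of `g`.
#' @export
window_ordering <- function(g, snp_indices, polarity) {
  stopifnot(length(snp_indices) == length(polarity))
  if (all(polarity == 0L)) stop("all-zero polarity vector", call. = FALSE)
  keep <- polarity != 0L
  idx <- snp_indices[keep]
  pol <- as.integer(polarity[keep])
  s_mats <- lapply(seq_along(idx), function(j) {
    unclass(snp_ordering(g$dosages[, idx[j]], pol[j]))
  })
  if (length(s_mats) == 1L) {
    w <- s_mats[[1]]
  } else {
    i_mats <- lapply(seq_len(length(s_mats) - 1L), function(j) {
      lambda2(s_mats[[j]], s_mats[[j + 1L]])
    })
    w <- lambda_combine(i_mats)
  }
  diag(w) <- 0L
  ordering_matrix(w)
}

#' Information content of an ordering matrix
#'
#' The proportion of off-diagonal subject pairs whose ordering is decided
#' (not `?`). Used as the regularization axis when choosing among polarity
#' assignments: a highly significant result supported by few decidable pairs
#' reflects a small unusual subset of subjects, not a population-level
#' signal.
#'
#' @param w an `ordering_matrix` (n >= 2).
#' @return fraction in `[0, 1]`.
#' @export
information_content <- function(w) {
  n <- nrow(w)
  stopifnot(n >= 2)
  decided <- sum(!is.na(w)) - n  # diagonal is always 0, excluded
  decided / (n * (n - 1))
}
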