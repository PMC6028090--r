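#' Construct a genotype matrix
#'
#' The central genotype container: an integer matrix of minor-allele dosages
#' (subjects in rows, SNPs in columns, `NA` = missing call) together with a
#' SNP annotation tibble. Spacer SNPs are all-missing pseudo-markers inserted
#' at LD-block boundaries so that no analysis window spans two blocks; they
#' are never tested.
#'
#' @param dosages integer matrix, subjects x SNPs, values in `{0, 1, 2, NA}`
#'   counting copies of the minor allele.
#' @param snps tibble with one row per SNP: `chrom` (character), `pos`
#'   (1-based integer position, strictly increasing within a chromosome),
#'   `id` (unique SNP identifier), and optionally `is_spacer` (logical,
#'   default all `FALSE`).
#' @param subjects character vector of subject identifiers, one per row of
#'   `dosages`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snps`, `subjects`.
#' @export
genotype_matrix <- function(dosages, snps, subjects = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  snps <- tibble::as_tibble(snps)
  if (!"is_spacer" %in% names(snps)) snps$is_spacer <- FALSE
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$id <- as.character(snps$id)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(dosages)))
  subjects <- as.character(subjects)

  if (ncol(dosages) != nrow(snps)) {
    stop("`dosages` has ", ncol(dosages), " columns but `snps` has ",
         nrow(snps), " rows", call. = FALSE)
  }
  if (nrow(dosages) != length(subjects)) {
    stop("`dosages` has ", nrow(dosages), " rows but `subjects` has length ",
         length(subjects), call. = FALSE)
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("dosage codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(snps$id)) {
    stop("duplicate SNP ids: ",
         paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "),
         call. = FALSE)
  }
  incr <- unlist(lapply(split(snps$pos, factor(snps$chrom, unique(snps$chrom))),
                        function(p) diff(p) > 0), use.names = FALSE)
  if (length(incr) && !all(incr)) {
    stop("`pos` must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  if (any(snps$is_spacer)) {
    sp <- which(snps$is_spacer)
    if (!all(is.na(dosages[, sp]))) {
      stop("spacer SNPs must have all-missing dosages", call. = FALSE)
    }
  }
  rownames(dosages) <- subjects
  colnames(dosages) <- snps$id
  structure(
    list(dosages = dosages, snps = snps, subjects = subjects),
    class = "genotype_matrix"
  )
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  n_sp <- sum(x$snps$is_spacer)
  cat("<genotype_matrix> ", length(x$subjects), " subjects x ",
      nrow(x$snps), " SNPs", if (n_sp) paste0(" (", n_sp, " spacers)"),
      ", ", length(unique(x$snps$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$dosages[, !x$snps$is_spacer, drop = FALSE]))
  cat("  missing call rate (non-spacer): ", format(round(miss, 4)), "\n",
      sep = "")
  invisible(x)
}

#' @method dim genotype_matrix
#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

n_subjects <- function(g) length(g$subjects)
n_snps <- function(g) nrow(g$snps)

# subset columns (SNPs), keeping invariants
subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$snps[keep, , drop = FALSE],
                  g$subjects)
}

#' Construct a phenotype table
#'
#' @param subject_id character vector of subject ids.
#' @param status integer vector of case/control status (1 = case, 0 = control).
#' @return A tibble with columns `subject_id`, `status`.
#' @export
phenotype_table <- function(subject_id, status) {
  status <- as.integer(status)
  if (!all(status %in% 0:1)) stop("status must be 0 or 1", call. = FALSE)
  if (length(subject_id) != length(status)) {
    stop("subject_id and status lengths differ", call. = FALSE)
  }
  m <- sum(status)
  if (m == 0L || m == length(status)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  tibble::tibble(subject_id = as.character(subject_id), status = status)
}

# Align a phenotype table to a genotype matrix, returning the 0/1 status
# vector in subject order. Errors if any subject is unphenotyped.
align_status <- function(g, phenotype) {
  if (is.numeric(phenotype) && is.null(dim(phenotype))) {
    status <- as.integer(phenotype)
    if (length(status) != length(g$subjects)) {
      stop("phenotype vector length does not match subject count",
           call. = FALSE)
    }
  } else {
    phenotype <- tibble::as_tibble(phenotype)
    idx <- match(g$subjects, phenotype$subject_id)
    if (anyNA(idx)) {
      stop("no phenotype for subject(s): ",
           paste(utils::head(g$subjects[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    status <- as.integer(phenotype$status[idx])
  }
  if (!all(status %in% 0:1)) stop("status must be 0 or 1", call. = FALSE)
  m <- sum(status)
  if (m == 0L || m == length(status)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  status
}
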