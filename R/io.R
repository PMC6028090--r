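#' Read a genotype matrix from VCF, PLINK text or TSV
#'
#' Dosages are always minor-allele counts computed from the sample set
#' itself: for each SNP the lower-frequency allele is "a". Exact 0.5
#' frequency ties are broken deterministically: VCF keeps ALT as the minor
#' allele, PLINK keeps the second-listed allele, and a TSV column is kept as
#' coded. SNPs are ordered by (chrom, pos); chromosomes keep their order of
#' first appearance.
#'
#' Formats:
#' * `tsv` — header row of SNP ids, first column `subject_id`, one row per
#'   subject, cells 0/1/2 or `NA`. A TSV carries no coordinates, so `chrom`
#'   is `"1"` and `pos` is the column index.
#' * `vcf` — GT field only; gzip allowed; multi-allelic records are skipped
#'   with a warning.
#' * `plink_text` — a `.ped`/`.map` pair; pass the `.ped` path or the common
#'   prefix. Allele code `0` = missing.
#'
#' @param path input file path (for PLINK, the `.ped` file or prefix).
#' @param format one of `"tsv"`, `"vcf"`, `"plink_text"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink_text")) {
  format <- match.arg(format)
  switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path),
    plink_text = read_genotypes_plink(path)
  )
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = c("NA", ""))
  if (ncol(tab) < 2L || names(tab)[1] != "subject_id") {
    stop("TSV format error in ", path,
         ": expected a 'subject_id' column followed by SNP columns",
         call. = FALSE)
  }
  subjects <- as.character(tab$subject_id)
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  bad <- which(!is.na(d) & !(d %in% 0:2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("TSV format error in ", path, ": non-dosage value at row ",
         bad[1, 1], ", column '", colnames(d)[bad[1, 2]], "'", call. = FALSE)
  }
  # recode columns where the coded allele is actually the major one
  f <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) d[, flip] <- 2L - d[, flip]
  genotype_matrix(
    d,
    tibble::tibble(chrom = "1", pos = seq_len(ncol(d)), id = colnames(d)),
    subjects
  )
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped", call. = FALSE)
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # alt-allele count per call; any missing allele -> NA
  alt_count <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".") || anyNA(al)) return(NA_integer_)
      sum(al != "0")
    }, integer(1))
  }
  d <- t(apply(gt, 1, function(row) {
    row[is.na(row)] <- "./."
    alt_count(row)
  }))
  f_alt <- rowMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(f_alt) & f_alt > 0.5   # tie (0.5) keeps ALT as minor
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  g <- genotype_matrix(
    t(d),
    tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids),
    colnames(gt)
  )
  sort_snps(g)
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (f in c(ped_path, map_path)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) {
    stop("format error in ", map_path, ": expected 4 columns", call. = FALSE)
  }
  names(map)[c(1, 2, 4)] <- c("chrom", "id", "pos")
  p <- nrow(map)
  lines <- readLines(ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(toks)
  if (length(unique(nfield)) != 1L || nfield[1] != 6L + 2L * p) {
    stop("format error in ", ped_path, ": line ",
         which(nfield != 6L + 2L * p)[1] %||% 1L,
         " has wrong field count (subject/SNP mismatch)", call. = FALSE)
  }
  subjects <- vapply(toks, `[[`, character(1), 2L)
  al <- do.call(rbind, lapply(toks, function(x) x[-(1:6)]))
  a1 <- al[, seq(1, 2 * p, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * p, by = 2), drop = FALSE]
  d <- matrix(NA_integer_, nrow(al), p)
  for (j in seq_len(p)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    seen <- unique(c(x1[!miss], x2[!miss]))  # order of appearance
    if (length(seen) > 2L) {
      stop("format error in ", ped_path, ": SNP ", map$id[j],
           " has >2 alleles", call. = FALSE)
    }
    if (length(seen) == 0L) { d[, j] <- NA_integer_; next }
    counted <- if (length(seen) == 1L) seen else {
      freq2 <- (sum(x1 == seen[2]) + sum(x2 == seen[2])) /
        (2 * sum(!miss))
      if (freq2 <= 0.5) seen[2] else seen[1]  # tie -> second-listed
    }
    d[, j] <- (x1 == counted) + (x2 == counted)
    d[miss, j] <- NA_integer_
  }
  g <- genotype_matrix(
    d,
    tibble::tibble(chrom = as.character(map$chrom), pos = map$pos,
                   id = map$id),
    subjects
  )
  sort_snps(g)
}

sort_snps <- function(g) {
  ord <- order(factor(g$snps$chrom, unique(g$snps$chrom)), g$snps$pos)
  subset_snps(g, ord)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of `read_genotypes(format = "tsv")` up to dosage values; spacer
#' SNPs are omitted (they are all-missing bookkeeping markers).
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(g, path) {
  keep <- !g$snps$is_spacer
  tab <- tibble::as_tibble(as.data.frame(g$dosages[, keep, drop = FALSE]),
                           .name_repair = "minimal")
  names(tab) <- g$snps$id[keep]
  tab <- dplyr::bind_cols(tibble::tibble(subject_id = g$subjects), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' GT-only records with placeholder alleles (REF = A, ALT = G, the ALT
#' being the counted minor allele), suitable for re-reading with
#' `read_genotypes(format = "vcf")`; chromosome and position are preserved,
#' spacer SNPs are omitted. Dosage `d` becomes an unphased genotype with
#' `d` ALT alleles; missing becomes `./.`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain text; use an uncompressed name).
#' @export
write_genotypes_vcf <- function(g, path) {
  keep <- which(!g$snps$is_spacer)
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$subjects), collapse = "\t")
  )
  body <- vapply(keep, function(j) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$id[j], "A", "G", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column TSV: `subject_id`, `status` (0 = control, 1 = case).
#' @param path file path.
#' @return tibble with `subject_id`, `status`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("subject_id", "status") %in% names(tab))) {
    stop("phenotype file must have columns subject_id, status", call. = FALSE)
  }
  phenotype_table(tab$subject_id, tab$status)
}

#' Read BED intervals (LD blocks or gene map)
#'
#' BED 3+1: chrom, start, end (0-based half-open), optional name. Intervals
#' are sorted and checked for overlap within a chromosome.
#' @param path file path.
#' @return tibble `chrom`, `start`, `end`, `name`.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, stringsAsFactors = FALSE, sep = "\t",
                           comment.char = "#")
  if (ncol(tab) < 3L) stop("BED file needs >=3 columns", call. = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  tab$name <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    paste0(tab$chrom, ":", tab$start, "-", tab$end)
  tab <- tibble::as_tibble(tab[, c("chrom", "start", "end", "name")])
  tab$chrom <- as.character(tab$chrom)
  tab <- dplyr::arrange(tab, factor(.data$chrom, unique(.data$chrom)),
                        .data$start)
  ovl <- tab |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      bad = any(.data$start[-1] < .data$end[-length(.data$end)])
    ) |>
    dplyr::pull(.data$bad)
  if (any(ovl, na.rm = TRUE)) {
    stop("overlapping intervals within a chromosome", call. = FALSE)
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
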