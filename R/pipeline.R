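#' Assemble a run configuration
#'
#' All knobs of the end-to-end pipeline in one validated list. The
#' serialized configuration (and its MD5 hash) is written into the header
#' of every output file, so any run can be reproduced from its outputs.
#' Unknown keys are rejected.
#'
#' @param genotypes path to the genotype file.
#' @param format genotype format (`"tsv"`, `"vcf"`, `"plink_text"`).
#' @param phenotypes path to the phenotype TSV.
#' @param ld_blocks optional path to a BED file of LD-block intervals.
#' @param out_dir output directory (created if absent).
#' @param maf_min,callrate_min,r2_max QC thresholds.
#' @param max_window,ic_min windowed-scan parameters.
#' @param agws_trim_top,agws_tol,agws_min_results aGWS parameters.
#' @param seed integer seed recorded in the outputs.
#' @param ... rejected; catches misspelled keys.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes, phenotypes, out_dir,
                       format = "tsv", ld_blocks = NULL,
                       maf_min = 0.01, callrate_min = 0.9, r2_max = 0.95,
                       max_window = 6L, ic_min = 0,
                       agws_trim_top = 0.01, agws_tol = 0.5,
                       agws_min_results = 10L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes,
         out_dir = out_dir, format = format, ld_blocks = ld_blocks,
         maf_min = maf_min, callrate_min = callrate_min, r2_max = r2_max,
         max_window = as.integer(max_window), ic_min = ic_min,
         agws_trim_top = agws_trim_top, agws_tol = agws_tol,
         agws_min_results = as.integer(agws_min_results),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

config_header <- function(cfg, hash) {
  c(paste0("# mugwas ", as.character(utils::packageVersion("mugwas"))),
    paste0("# config_md5: ", hash),
    paste0("# config: ", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                          null = "null")),
    "# sign convention: higher u-score = higher risk; two-sided p")
}

write_tsv_with_header <- function(tab, path, header) {
  readr::write_lines(header, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full association pipeline
#'
#' Reads genotypes and phenotypes, applies QC (SNP exclusion, neighbor-LD
#' pruning, spacer insertion at LD-block boundaries), runs the single-SNP
#' and windowed u-test scans, estimates both adaptive significance cutoffs,
#' and writes all results with the serialized configuration in every file
#' header. Reruns with the same config and seed are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) the output directory; side effects: `results_ss.tsv`,
#'   `results_mu.tsv`, `agws_ss.json`, `agws_mu.json`, `qr_ss.tsv`,
#'   `qr_mu.tsv`, `config.json`, `log.txt` in `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  hash <- unname(tools::md5sum(cfg_path))
  header <- config_header(cfg, hash)
  log_lines <- c(header, paste0("# R: ", R.version.string),
                 paste0("# seed: ", cfg$seed))

  set.seed(cfg$seed)
  g <- stage("read_genotypes", read_genotypes(cfg$genotypes, cfg$format))
  phen <- stage("read_phenotypes", read_phenotypes(cfg$phenotypes))
  log_lines <- c(log_lines,
                 sprintf("read: %d subjects x %d SNPs", nrow(g$dosages),
                         ncol(g$dosages)))

  g <- stage("filter_snps",
             withCallingHandlers(
               filter_snps(g, cfg$maf_min, cfg$callrate_min),
               message = function(m) {
                 log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
                 invokeRestart("muffleMessage")
               }))
  g <- stage("prune_adjacent_ld",
             withCallingHandlers(
               prune_adjacent_ld(g, cfg$r2_max),
               message = function(m) {
                 log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
                 invokeRestart("muffleMessage")
               }))
  blocks <- if (!is.null(cfg$ld_blocks)) {
    stage("read_ld_blocks", read_bed_intervals(cfg$ld_blocks))
  } else NULL
  g <- stage("insert_block_spacers",
             insert_block_spacers(g, blocks, cfg$max_window))

  res_ss <- stage("single_snp_gwas", single_snp_gwas(g, phen))
  res_mu <- stage("mu_gwas",
                  mu_gwas(g, phen, cfg$max_window, cfg$ic_min))

  agws_args <- function(res, an) {
    agws_cutoff(res, analysis = an, trim_top = cfg$agws_trim_top,
                tol = cfg$agws_tol, min_results = cfg$agws_min_results)
  }
  agws_ss <- stage("agws_ss", agws_args(res_ss, "ss"))
  agws_mu <- stage("agws_mu", agws_args(res_mu, "mu"))

  out <- function(x) file.path(cfg$out_dir, x)
  write_tsv_with_header(res_ss, out("results_ss.tsv"), header)
  write_tsv_with_header(
    dplyr::select(res_mu, -dplyr::any_of(c("win_start", "pol_key"))),
    out("results_mu.tsv"), header)
  write_agws_json(agws_ss, out("agws_ss.json"))
  write_agws_json(agws_mu, out("agws_mu.json"))
  write_tsv_with_header(qr_plot_data(agws_ss), out("qr_ss.tsv"), header)
  write_tsv_with_header(qr_plot_data(agws_mu), out("qr_mu.tsv"), header)
  log_lines <- c(
    log_lines,
    sprintf("aGWS (ss): %.4f  aGWS/2: %.4f", agws_ss$agws,
            agws_ss$agws_half),
    sprintf("aGWS (mu): %.4f  aGWS/2: %.4f", agws_mu$agws,
            agws_mu$agws_half),
    sprintf("results above aGWS: ss %d, mu %d",
            sum(res_ss$s > agws_ss$agws), sum(res_mu$s > agws_mu$agws))
  )
  readr::write_lines(log_lines, out("log.txt"))
  invisible(cfg$out_dir)
}

#' Cross-study replication check
#'
#' For every result in study A above A's adaptive cutoff, looks for
#' supportive evidence in study B at B's `aGWS / 2` replication threshold:
#' at the same SNP, within the same gene interval (if a gene map is given),
#' or within a flanking window. The first tier that matches labels the
#' result.
#'
#' @param results_a,results_b results tibbles.
#' @param agws_a,agws_b matching `agws_result` objects (or numeric cutoffs).
#' @param gene_map optional BED tibble (`chrom`, `start`, `end`, `name`).
#' @param flank flanking window in bp for the positional tier
#'   (default 10000).
#' @return tibble of A's significant results with `tier` in
#'   `c("same-SNP", "same-gene", "flank", "not replicated")` plus the best
#'   supporting B result.
#' @export
replication_check <- function(results_a, agws_a, results_b, agws_b,
                              gene_map = NULL, flank = 10000L) {
  cut_a <- if (inherits(agws_a, "agws_result")) agws_a$agws else agws_a
  cut_b <- if (inherits(agws_b, "agws_result")) agws_b$agws_half else
    agws_b / 2
  hits <- results_a[results_a$s > cut_a, , drop = FALSE]
  support <- results_b[results_b$s > cut_b, , drop = FALSE]

  gene_of <- function(chrom, pos) {
    if (is.null(gene_map)) return(NA_character_)
    hit <- which(gene_map$chrom == chrom & gene_map$start <= pos - 1L &
                   pos - 1L < gene_map$end)
    if (length(hit)) gene_map$name[hit[1]] else NA_character_
  }

  rows <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    tier <- "not replicated"
    support_id <- NA_character_
    support_s <- NA_real_
    same_snp <- support$snp_id == h$snp_id
    if (any(same_snp)) {
      tier <- "same-SNP"
      j <- which(same_snp)[which.max(support$s[same_snp])]
    } else {
      gene_a <- gene_of(h$chrom, h$pos)
      gene_b <- vapply(seq_len(nrow(support)), function(k) {
        gene_of(support$chrom[k], support$pos[k])
      }, character(1))
      in_gene <- !is.na(gene_a) & !is.na(gene_b) & gene_b == gene_a
      near <- support$chrom == h$chrom & abs(support$pos - h$pos) <= flank
      if (any(in_gene)) {
        tier <- "same-gene"
        j <- which(in_gene)[which.max(support$s[in_gene])]
      } else if (any(near)) {
        tier <- "flank"
        j <- which(near)[which.max(support$s[near])]
      } else j <- NA_integer_
    }
    if (!is.na(j)) {
      support_id <- support$snp_id[j]
      support_s <- support$s[j]
    }
    tibble::tibble(chrom = h$chrom, pos = h$pos, snp_id = h$snp_id,
                   s = h$s, tier = tier, support_snp = support_id,
                   support_s = support_s)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(chrom = character(), pos = integer(),
                           snp_id = character(), s = numeric(),
                           tier = character(), support_snp = character(),
                           support_s = numeric())
  }
  rows
}
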