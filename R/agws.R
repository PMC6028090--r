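#' Quantile-rank points for one chromosome
#'
#' Orders a chromosome's s-values (`-log10 p`) ascending and assigns
#' normalized ranks `x_i = (i - 0.5) / N`. Because allele counts are bounded,
#' the attainable p-value of a SNP depends on its MAF, so the null QR curve
#' of a chromosome is a mixture of bounded univariate distributions — a
#' convex curve rather than the straight line classical QQ intuition
#' suggests.
#'
#' @param results a results tibble with columns `chrom` and `s`.
#' @param chrom chromosome label.
#' @param min_results chromosomes with fewer results are rejected
#'   (default 10).
#' @return tibble with `x` (ranks) and `s` (ascending).
#' @export
qr_points <- function(results, chrom, min_results = 10L) {
  s <- results$s[results$chrom == chrom]
  n <- length(s)
  if (n < min_results) {
    stop("chromosome ", chrom, " has ", n, " results (need >= ",
         min_results, ")", call. = FALSE)
  }
  tibble::tibble(x = (seq_len(n) - 0.5) / n, s = sort(s))
}

#' Shape-constrained convex fit to a QR curve
#'
#' Least-squares fit of a non-decreasing convex function to `(x, s)`,
#' excluding the top `trim_top` fraction of ranks (where true associations
#' and outliers live) and extending the fit over the trimmed range by linear
#' continuation of the last segment's slope (the "projection"). The fit is a
#' piecewise-linear function `f(x) = b0 + b1 (x - x0) + sum_j g_j (x - k_j)+`
#' with `b1, g_j >= 0`, solved as a non-negative least-squares problem, so
#' monotonicity and convexity hold by construction.
#'
#' @param x normalized ranks, increasing.
#' @param s s-values, ascending.
#' @param trim_top fraction of top ranks excluded from the fit
#'   (default 0.01).
#' @param n_knots maximum number of interior hinge knots (default 40).
#' @return object of class `convex_fit`: list with `x`, `s`, `fitted` (full
#'   grid including the projected range), `apex` (fitted value at the top
#'   rank), `n_fit`, `trim_top`.
#' @export
convex_fit <- function(x, s, trim_top = 0.01, n_knots = 40L) {
  stopifnot(length(x) == length(s), !is.unsorted(s), trim_top >= 0,
            trim_top < 0.5)
  n <- length(x)
  n_trim <- floor(trim_top * n)
  n_fit <- n - n_trim
  if (n_fit < 4L) stop("fewer than 4 points after trimming", call. = FALSE)
  xf <- x[seq_len(n_fit)]
  sf <- s[seq_len(n_fit)]
  x0 <- xf[1]

  # knot placement: a null QR curve behaves like -log10(1 - x), with its
  # curvature concentrated near the top rank, so uniform knots alone cannot
  # track the tail; half the knots are spaced uniformly over the fitted
  # ranks and half geometrically densified toward the upper end
  knots <- unique(xf[-c(1L, n_fit)])
  if (length(knots) > n_knots) {
    k_half <- max(2L, n_knots %/% 2L)
    uniform <- stats::quantile(knots, probs = seq_len(k_half) / (k_half + 1),
                               names = FALSE, type = 1)
    tail_idx <- unique(pmax(1L, n_fit - 1L - 2L^(0:ceiling(log2(n_fit)))))
    tail_idx <- tail_idx[tail_idx > 1L & tail_idx < n_fit]
    knots <- sort(unique(c(uniform, xf[tail_idx])))
  }
  basis <- function(xx) {
    hinges <- vapply(knots, function(k) pmax(xx - k, 0), numeric(length(xx)))
    cbind(1, -1, xx - x0, hinges)
  }
  a <- basis(xf)
  coef <- pracma::lsqnonneg(a, sf)$x
  fitted <- as.numeric(basis(x) %*% coef)
  structure(
    list(x = x, s = s, fitted = fitted, apex = fitted[n], coef = coef,
         knots = knots, n_fit = n_fit, trim_top = trim_top),
    class = "convex_fit"
  )
}

#' @method print convex_fit
#' @export
print.convex_fit <- function(x, ...) {
  cat("<convex_fit> ", length(x$x), " points (", x$n_fit, " fitted), apex ",
      format(round(x$apex, 3)), "\n", sep = "")
  invisible(x)
}

#' Count points rising above a convex fit
#'
#' @param x,s QR points.
#' @param fit a `convex_fit` (its projection covers the trimmed range).
#' @param tol tolerance in s-units before a point counts as an outlier
#'   (default 0.5).
#' @return integer count.
#' @export
count_outliers <- function(x, s, fit, tol = 0.5) {
  stopifnot(length(s) == length(fit$fitted))
  sum(s > fit$fitted + tol)
}

#' Adaptive genome-wide significance cutoff
#'
#' Estimates the study-specific significance cutoff from per-chromosome
#' QR curves: each chromosome gets a convex fit; the half of chromosomes
#' with the fewest outliers above their fit (tie-break: smaller apex) is
#' taken to represent the null expectation — chromosomes carrying true
#' association have concave tops and many outliers and are excluded — and
#' the cutoff is the median apex of the selected chromosomes. Results above
#' `agws` are study-wide significant; `agws / 2` is the threshold for
#' replication support in an independent cohort.
#'
#' @param results results tibble (one selected result per center SNP for the
#'   windowed analysis).
#' @param analysis label stored in the result (`"ss"` or `"mu"`; default
#'   taken from the table).
#' @param trim_top,tol,min_results see [convex_fit()], [count_outliers()],
#'   [qr_points()].
#' @return object of class `agws_result`: per-chromosome curve summary
#'   (`tidy()`), cutoffs (`glance()`), fits, and `agws`, `agws_half`.
#' @export
agws_cutoff <- function(results, analysis = NULL, trim_top = 0.01,
                        tol = 0.5, min_results = 10L) {
  analysis <- analysis %||%
    (if ("analysis" %in% names(results)) results$analysis[1] else "ss")
  results$chrom <- as.character(results$chrom)
  chroms <- unique(results$chrom)
  counts <- table(factor(results$chrom, chroms))
  small <- names(counts)[counts < min_results]
  if (length(small)) {
    warning("excluding chromosome(s) with < ", min_results, " results: ",
            paste(small, collapse = ", "), call. = FALSE)
    chroms <- setdiff(chroms, small)
  }
  if (length(chroms) < 4L) {
    stop("need >= 4 chromosomes with enough results for a per-chromosome ",
         "aGWS estimate; pool chromosomes or lower min_results",
         call. = FALSE)
  }
  fits <- lapply(chroms, function(ch) {
    qr <- qr_points(results, ch, min_results)
    fit <- convex_fit(qr$x, qr$s, trim_top = trim_top)
    list(chrom = ch, qr = qr, fit = fit,
         n_outliers = count_outliers(qr$x, qr$s, fit, tol))
  })
  curves <- tibble::tibble(
    chrom = vapply(fits, `[[`, character(1), "chrom"),
    n = vapply(fits, function(f) nrow(f$qr), integer(1)),
    n_outliers = vapply(fits, `[[`, integer(1), "n_outliers"),
    apex = vapply(fits, function(f) f$fit$apex, numeric(1))
  )
  k <- ceiling(nrow(curves) / 2)
  sel <- order(curves$n_outliers, curves$apex)[seq_len(k)]
  curves$selected <- seq_len(nrow(curves)) %in% sel
  agws <- stats::median(curves$apex[curves$selected])
  structure(
    list(curves = curves, fits = fits, agws = agws, agws_half = agws / 2,
         analysis = analysis,
         params = list(trim_top = trim_top, tol = tol,
                       min_results = min_results)),
    class = "agws_result"
  )
}

#' @method print agws_result
#' @export
print.agws_result <- function(x, ...) {
  cat("<agws_result> [", x$analysis, "] ", nrow(x$curves),
      " chromosome(s), ", sum(x$curves$selected), " selected\n",
      "  aGWS = ", format(round(x$agws, 4)),
      "  (replication threshold aGWS/2 = ",
      format(round(x$agws_half, 4)), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname agws_cutoff
#' @param x an `agws_result`.
#' @param ... unused.
#' @export
tidy.agws_result <- function(x, ...) x$curves

#' @rdname agws_cutoff
#' @export
glance.agws_result <- function(x, ...) {
  tibble::tibble(
    analysis = x$analysis,
    n_chrom = nrow(x$curves),
    n_selected = sum(x$curves$selected),
    agws = x$agws,
    agws_half = x$agws_half
  )
}

#' Export an aGWS result as JSON
#'
#' @param x an `agws_result`.
#' @param path output path.
#' @export
write_agws_json <- function(x, path) {
  jsonlite::write_json(
    list(analysis = x$analysis, agws = x$agws, agws_half = x$agws_half,
         params = x$params, chromosomes = x$curves),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' QR plot data for external plotting
#'
#' One row per result per chromosome: rank, observed s, fitted expectation.
#' @param x an `agws_result`.
#' @return tibble `chrom`, `x`, `s`, `fit`, `selected`.
#' @export
qr_plot_data <- function(x) {
  curves <- x$curves
  purrr::map_dfr(x$fits, function(f) {
    sel <- curves$selected[curves$chrom == f$chrom]
    tibble::tibble(chrom = f$chrom, x = f$qr$x, s = f$qr$s,
                   fit = f$fit$fitted, selected = sel)
  })
}
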