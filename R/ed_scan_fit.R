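#' Fit an Euclidean-distance genome scan
#'
#' The one-stop scan: takes two-bulk variant sites, optionally applies
#' the proximity and locus filters, scores each surviving SNP with the
#' Euclidean-distance statistic raised to \code{power}, fits sliding-
#' window averages along every chromosome, sets the genome-wide
#' \code{median + n_sd * SD} threshold, and calls candidate regions.
#'
#' @param sites a \code{\link{bulk_sites}} table (e.g. from
#'   \code{\link{read_bulk_vcf}} or \code{\link{simulate_bulk_reads}}).
#' @param power exponent on ED (default 5).
#' @param window sliding-window width in bp (default 1 Mb).
#' @param step window step in bp (default \code{window/100}).
#' @param min_snps minimum SNPs per defined window (default 10).
#' @param n_sd standard deviations above the genome-wide median (default 3).
#' @param gap_tolerance undefined windows bridged inside a peak run.
#' @param mask optional data frame (chrom, start, end, 1-based inclusive)
#'   of repetitive regions whose SNPs are excluded before scoring;
#'   \code{NULL} (default) leaves the genome unmasked.
#' @param filter apply \code{\link{filter_variant_proximity}} and
#'   \code{\link{filter_ed_input}} first (default TRUE); set FALSE if
#'   \code{sites} are already filtered.
#' @param min_alt_reads,hom_threshold passed to
#'   \code{\link{filter_ed_input}}.
#' @param chrom_lengths named vector; defaults to the sites' attribute.
#'
#' @return an object of class \code{ed_scan} with components
#'   \code{scores} (per-SNP ED table), \code{track} (fitted windows),
#'   \code{threshold}, \code{regions}, \code{filters} (reports, when
#'   run) and \code{params}. Methods: \code{print}, \code{summary},
#'   \code{plot}.
#' @examples
#' cfg <- sim_config(chrom_lengths = c(c1 = 4e6), marker_spacing = 2e4,
#'                   causal_pos = 2e6, seed = 7)
#' sim <- simulate_bsa(cfg, n_population = 150)
#' scan <- ed_scan(sim$sites, window = 5e5)
#' scan$regions
#' @export
ed_scan <- function(sites, power = 5, window = 1e6, step = window / 100,
                    min_snps = 10, n_sd = 3, gap_tolerance = 0, mask = NULL,
                    filter = TRUE, min_alt_reads = 2, hom_threshold = 0.05,
                    chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- attr(sites, "chrom_lengths")
  filters <- NULL
  if (filter) {
    prox <- filter_variant_proximity(sites)
    loc <- filter_ed_input(prox$sites, min_alt_reads = min_alt_reads,
                           hom_threshold = hom_threshold)
    filters <- list(proximity = prox, ed_input = loc)
    sites <- loc$sites
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    keep <- rep(TRUE, nrow(sites))
    for (i in seq_len(nrow(mask))) {
      keep <- keep & !(sites$chrom == mask$chrom[i] &
                         sites$pos >= mask$start[i] & sites$pos <= mask$end[i])
    }
    sites <- sites[keep, , drop = FALSE]
  }
  if (nrow(sites) == 0)
    stop("no SNPs left to score after filtering/masking", call. = FALSE)

  scores <- ed_statistic(sites, power = power)
  track <- sliding_window_fit(scores, window = window, step = step,
                              min_snps = min_snps,
                              chrom_lengths = chrom_lengths)
  threshold <- ed_threshold(track, n_sd = n_sd)
  regions <- call_candidate_regions(track, threshold, scores = scores,
                                    gap_tolerance = gap_tolerance)
  structure(list(
    scores = scores, track = track, threshold = threshold, regions = regions,
    filters = filters,
    params = list(power = power, window = window, step = step,
                  min_snps = min_snps, n_sd = n_sd,
                  gap_tolerance = gap_tolerance, masked = !is.null(mask),
                  min_alt_reads = min_alt_reads, hom_threshold = hom_threshold)
  ), class = "ed_scan")
}

#' @export
print.ed_scan <- function(x, ...) {
  p <- x$params
  cat("Euclidean-distance genome scan\n")
  cat(sprintf("  %d SNPs scored; ED^%g smoothed in %.3g-Mb windows (step %.3g kb)\n",
              nrow(x$scores), p$power, p$window / 1e6, p$step / 1e3))
  cat(sprintf("  threshold: median %.4g + %g SD = %.4g\n",
              x$threshold$median, p$n_sd, x$threshold$tau))
  if (nrow(x$regions) == 0) {
    cat("  no candidate regions above threshold\n")
  } else {
    cat(sprintf("  %d candidate region(s):\n", nrow(x$regions)))
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      cat(sprintf("    %s:%s-%s (%.2f Mb, %d SNPs, peak %.4g)\n",
                  r$chrom, format(r$start, big.mark = ","),
                  format(r$end, big.mark = ","), r$length / 1e6, r$n_snps,
                  r$peak))
    }
  }
  invisible(x)
}

#' @export
summary.ed_scan <- function(object, ...) {
  s <- list(
    n_snps = nrow(object$scores),
    ed_quartiles = stats::quantile(object$scores$ed, c(0.25, 0.5, 0.75)),
    threshold = object$threshold,
    n_windows = nrow(object$track),
    n_defined = sum(!is.na(object$track$value)),
    regions = object$regions,
    filters = if (!is.null(object$filters))
      lapply(object$filters, filter_report_summary),
    params = object$params)
  class(s) <- "summary.ed_scan"
  s
}

#' @export
print.summary.ed_scan <- function(x, ...) {
  cat(sprintf("ED scan summary: %d SNPs, %d/%d windows defined\n",
              x$n_snps, x$n_defined, x$n_windows))
  cat(sprintf("  ED quartiles: %.4g / %.4g / %.4g\n",
              x$ed_quartiles[1], x$ed_quartiles[2], x$ed_quartiles[3]))
  print(x$threshold)
  if (!is.null(x$filters)) {
    f <- x$filters
    cat(sprintf("  filters: %d removed by proximity rules, %d by locus rules\n",
                f$proximity$n_removed, f$ed_input$n_removed))
  }
  cat(sprintf("  %d candidate region(s)\n", nrow(x$regions)))
  if (nrow(x$regions) > 0) print.data.frame(x$regions)
  invisible(x)
}

#' Plot the fitted ED track
#'
#' One panel per chromosome: the sliding-window fitted values of powered
#' ED with the genome-wide threshold line and candidate regions shaded.
#'
#' @param x an \code{ed_scan}.
#' @param chroms chromosomes to draw (default all).
#' @param ... passed to \code{plot.default}.
#' @export
plot.ed_scan <- function(x, chroms = NULL, ...) {
  track <- x$track
  if (is.null(chroms)) chroms <- unique(track$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ylim <- range(c(track$value, x$threshold$tau), na.rm = TRUE)
  for (ch in chroms) {
    t <- track[track$chrom == ch, ]
    graphics::plot(t$center / 1e6, t$value, type = "l", ylim = ylim,
                   xlab = sprintf("%s position (Mb)", ch),
                   ylab = sprintf("mean ED^%g", x$params$power),
                   main = ch, ...)
    r <- x$regions[x$regions$chrom == ch, ]
    if (nrow(r) > 0) {
      graphics::rect(r$start / 1e6, ylim[1], r$end / 1e6, ylim[2],
                     col = grDevices::adjustcolor("tomato", 0.25), border = NA)
    }
    graphics::abline(h = x$threshold$tau, lty = 2, col = "firebrick")
  }
  invisible(x)
}
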