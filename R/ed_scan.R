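#' Per-base read frequencies of the two bulks
#'
#' Converts the per-base read counts at each site into frequency vectors
#' (count / total depth per bulk). Both bulks must have positive depth at
#' every site — zero-depth loci are the job of
#' \code{\link{filter_ed_input}} and reaching this function with one is a
#' contract violation.
#'
#' @param sites a \code{\link{bulk_sites}} table with positive depth in
#'   both bulks.
#' @return list with \code{n x 4} frequency matrices \code{$r01} and
#'   \code{$r02} (columns A, C, G, T); rows sum to one.
#' @export
base_frequencies <- function(sites) {
  c1 <- as.matrix(sites[paste0(BASES, "_R01")])
  c2 <- as.matrix(sites[paste0(BASES, "_R02")])
  dimnames(c1) <- dimnames(c2) <- list(NULL, BASES)
  d1 <- rowSums(c1)
  d2 <- rowSums(c2)
  if (any(d1 == 0) || any(d2 == 0))
    stop("zero-depth site reached base_frequencies(); run filter_ed_input() first",
         call. = FALSE)
  list(r01 = c1 / d1, r02 = c2 / d2)
}

#' Euclidean-distance association statistic
#'
#' At each SNP the statistic is the Euclidean distance between the two
#' bulks' base-frequency vectors,
#' \deqn{ED = \sqrt{(A_{R01}-A_{R02})^2 + (C_{R01}-C_{R02})^2 +
#'                  (G_{R01}-G_{R02})^2 + (T_{R01}-T_{R02})^2},}
#' where each symbol is the frequency of that base among the bulk's
#' reads. ED is 0 when the bulks agree and \eqn{\sqrt 2} when they are
#' fixed for different bases. Raising ED to a power (default 5)
#' suppresses sampling background relative to true association peaks
#' before smoothing.
#'
#' @param sites filtered \code{\link{bulk_sites}} (SNP-class, positive
#'   depth in both bulks).
#' @param power exponent applied to ED (\code{>= 1}).
#' @return a \code{site_scores} data frame: chromosome, position,
#'   \code{ed}, \code{ed_pow} and per-bulk depths.
#' @examples
#' s <- bulk_sites(data.frame(
#'   chrom = "c1", pos = 100L, ref = "A", alt = "T", class = "SNP",
#'   A_R01 = 10L, C_R01 = 0L, G_R01 = 0L, T_R01 = 0L,
#'   A_R02 = 0L, C_R02 = 0L, G_R02 = 0L, T_R02 = 10L))
#' ed_statistic(s)$ed  # sqrt(2)
#' @export
ed_statistic <- function(sites, power = 5) {
  if (!is.finite(power) || power < 1)
    stop("power must be >= 1", call. = FALSE)
  f <- base_frequencies(sites)
  ed <- sqrt(rowSums((f$r01 - f$r02)^2))
  d <- .site_depths(sites)
  out <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    ed = ed, ed_pow = ed^power,
    dp_R01 = as.integer(d$r01), dp_R02 = as.integer(d$r02),
    stringsAsFactors = FALSE)
  attr(out, "power") <- power
  attr(out, "chrom_lengths") <- attr(sites, "chrom_lengths")
  class(out) <- c("site_scores", class(out))
  out
}

#' Sliding-window fit of the powered ED signal
#'
#' Smooths the per-SNP powered ED along each chromosome: window centers
#' are stepped by \code{step} from \code{window/2} to
#' \code{length - window/2}, and the fitted value at a center \code{c} is
#' the mean powered ED of SNPs with position in
#' \code{[c - window/2, c + window/2)}. Windows holding fewer than
#' \code{min_snps} SNPs are emitted with value \code{NA} (undefined)
#' rather than zero, so sparse stretches do not fake troughs.
#'
#' @param scores a \code{site_scores} table, sorted by position within
#'   chromosome.
#' @param window window width in bp (default 1 Mb).
#' @param step distance between window centers (default \code{window/100}).
#' @param min_snps minimum SNPs for a window to be defined (default 10).
#' @param chrom_lengths named vector of chromosome lengths; taken from
#'   the scores' attribute or, failing that, the last SNP position.
#' @return a \code{fitted_track} data frame: chromosome, window center,
#'   fitted \code{value} (mean powered ED, NA when undefined) and
#'   contributing SNP count.
#' @export
sliding_window_fit <- function(scores, window = 1e6, step = window / 100,
                               min_snps = 10, chrom_lengths = NULL) {
  if (window <= 0 || step <= 0 || step > window)
    stop("need window > 0 and 0 < step <= window", call. = FALSE)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(scores, "chrom_lengths")

  tracks <- lapply(unique(scores$chrom), function(ch) {
    s <- scores[scores$chrom == ch, , drop = FALSE]
    pos <- s$pos
    if (is.unsorted(pos)) stop("scores must be position-sorted within chromosome",
                               call. = FALSE)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(pos)
    centers <- if (len >= window) seq(window / 2, len - window / 2, by = step)
      else len / 2
    csum <- c(0, cumsum(s$ed_pow))
    # half-open window [c - w/2, c + w/2); positions are integers so the
    # -0.5 offsets make findInterval match the boundary convention exactly
    lo <- findInterval(centers - window / 2 - 0.5, pos)
    hi <- findInterval(centers + window / 2 - 0.5, pos)
    cnt <- hi - lo
    val <- ifelse(cnt >= min_snps, (csum[hi + 1] - csum[lo + 1]) / pmax(cnt, 1),
                  NA_real_)
    data.frame(chrom = ch, center = centers, value = val, n_snps = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "min_snps") <- min_snps
  class(out) <- c("fitted_track", class(out))
  out
}

#' Genome-wide peak-calling threshold
#'
#' The threshold is \code{median + 3 * SD} of all defined fitted values
#' across the genome, with the sample (n-1) standard deviation. Windows
#' left undefined by the minimum-SNP rule do not contribute.
#'
#' @param track a \code{fitted_track} (genome-wide).
#' @param n_sd number of standard deviations above the median (default 3).
#' @return list of class \code{ed_threshold} with \code{$median},
#'   \code{$sd} and \code{$tau}.
#' @examples
#' tr <- data.frame(chrom = "c", center = 1:5, value = c(1, 2, 3, 4, 5),
#'                  n_snps = 10L)
#' ed_threshold(tr)$tau  # 3 + 3 * sd(1:5) = 7.743416
#' @export
ed_threshold <- function(track, n_sd = 3) {
  v <- track$value[!is.na(track$value)]
  if (length(v) < 2)
    stop("need at least 2 defined windows to set a threshold", call. = FALSE)
  med <- stats::median(v)
  s <- stats::sd(v)
  structure(list(median = med, sd = s, tau = med + n_sd * s, n_sd = n_sd),
            class = "ed_threshold")
}

#' @export
print.ed_threshold <- function(x, ...) {
  cat(sprintf("ED threshold: median %.6g + %g * SD %.6g = %.6g\n",
              x$median, x$n_sd, x$sd, x$tau))
  invisible(x)
}

candidate_regions <- function(df) {
  if (nrow(df) > 0) {
    stopifnot(all(df$start <= df$end))
    df$length <- df$end - df$start + 1
  } else {
    df$length <- numeric(0)
  }
  rownames(df) <- NULL
  class(df) <- unique(c("candidate_regions", class(df)))
  df
}

#' Call candidate regions above the threshold
#'
#' Maximal runs of consecutive defined windows with fitted value strictly
#' greater than the threshold are merged into one region per run. Runs
#' interrupted by at most \code{gap_tolerance} undefined windows are
#' bridged (default 0: any break ends the run). Each region spans from
#' the left edge of its first window to the right edge of its last and
#' is then clipped to the first/last contributing SNP, so reported
#' boundaries are base-pair-resolved.
#'
#' @param track a \code{fitted_track}.
#' @param threshold an \code{\link{ed_threshold}} or a bare number.
#' @param scores the \code{site_scores} used to build the track
#'   (optional; enables SNP-resolved boundaries and SNP counts).
#' @param gap_tolerance undefined windows allowed inside a run.
#' @return a \code{candidate_regions} data frame: chromosome, 1-based
#'   inclusive start/end, peak fitted value, SNP count, length in bp.
#' @export
call_candidate_regions <- function(track, threshold, scores = NULL,
                                   gap_tolerance = 0) {
  tau <- if (inherits(threshold, "ed_threshold")) threshold$tau
    else as.numeric(threshold)
  window <- attr(track, "window")
  if (is.null(window)) {
    # infer from center spacing when the track was built elsewhere
    window <- if (nrow(track) > 1) 2 * min(track$center) else 1
  }

  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    t <- t[order(t$center), , drop = FALSE]
    above <- !is.na(t$value) & t$value > tau
    if (!any(above)) next
    undef <- is.na(t$value)

    # group indices of above-threshold windows, bridging short undefined gaps
    idx <- which(above)
    brk <- c(TRUE, vapply(seq_along(idx)[-1], function(k) {
      between <- (idx[k - 1] + 1):(idx[k] - 1)
      if (length(between) == 0 || idx[k] - idx[k - 1] == 1) return(FALSE)
      # bridge only if every intervening window is undefined and few enough
      !(all(undef[between]) && length(between) <= gap_tolerance)
    }, logical(1)))
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      run <- idx[grp == g]
      left <- max(1, t$center[min(run)] - window / 2)
      right <- t$center[max(run)] + window / 2 - 1
      peak <- max(t$value[run])
      if (!is.null(scores)) {
        p <- scores$pos[scores$chrom == ch & scores$pos >= left &
                          scores$pos <= right]
        if (length(p)) {
          left <- min(p); right <- max(p)
          n_snps <- length(p)
        } else n_snps <- 0L
      } else {
        n_snps <- sum(t$n_snps[run])
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = left, end = right, peak = peak,
        n_snps = n_snps, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(candidate_regions(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      peak = numeric(), n_snps = integer(), stringsAsFactors = FALSE)))
  }
  df <- do.call(rbind, out)
  candidate_regions(.merge_overlapping_regions(df, scores))
}

# windows are much wider than the step, so two distinct runs can claim
# overlapping genomic spans; merge those into one region
.merge_overlapping_regions <- function(df, scores) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  keep <- list()
  cur <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    nxt <- df[i, ]
    if (nxt$chrom == cur$chrom && nxt$start <= cur$end) {
      cur$end <- max(cur$end, nxt$end)
      cur$peak <- max(cur$peak, nxt$peak)
      cur$n_snps <- if (!is.null(scores)) {
        sum(scores$chrom == cur$chrom & scores$pos >= cur$start &
              scores$pos <= cur$end)
      } else cur$n_snps + nxt$n_snps
    } else {
      keep[[length(keep) + 1]] <- cur
      cur <- nxt
    }
  }
  keep[[length(keep) + 1]] <- cur
  do.call(rbind, keep)
}
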