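#' Variant proximity filters
#'
#' Removes variant calls that are unreliable because of local crowding,
#' evaluated against the unfiltered input (rules do not cascade):
#' \enumerate{
#'   \item \emph{indel pair}: both indels of any same-chromosome pair
#'     closer than 10 bp (VCF POS distance) are removed;
#'   \item \emph{SNP cluster}: every SNP lying in any 5-bp window
#'     (positions \code{p..p+4}) that contains more than two SNPs is
#'     removed;
#'   \item \emph{SNP near indel}: every SNP within 5 bp of an indel is
#'     removed (the indel itself is kept unless rule 1 applies).
#' }
#' A site matched by several rules is reported once, under the first
#' matching rule in the order above. Filtering is idempotent.
#'
#' @param sites a \code{\link{bulk_sites}} table sorted by
#'   (chromosome, position).
#' @return a \code{filter_report}: list with the surviving \code{$sites},
#'   a \code{$removed} table of (chrom, pos, reason), and per-rule
#'   \code{$counts}.
#' @export
filter_variant_proximity <- function(sites) {
  .check_sorted(sites)
  n <- nrow(sites)
  reason <- rep(NA_character_, n)

  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    pos <- sites$pos[rows]
    is_snp <- sites$class[rows] == "SNP"

    ind <- which(!is_snp)
    if (length(ind) >= 2) {
      ip <- pos[ind]
      close_pair <- diff(ip) < 10
      hit <- unique(c(ind[which(close_pair)], ind[which(close_pair) + 1L]))
      reason[rows[hit]] <- ifelse(is.na(reason[rows[hit]]),
                                  "indel_pair", reason[rows[hit]])
    }

    snp <- which(is_snp)
    if (length(snp) >= 3) {
      sp <- pos[snp]
      # a window with > 2 SNPs can always be slid left onto a SNP, so
      # windows anchored at SNP positions suffice
      hi <- findInterval(sp + 4, sp)
      lo <- seq_along(sp)
      bad <- which(hi - lo + 1L >= 3L)
      if (length(bad)) {
        in_cluster <- rep(FALSE, length(sp))
        for (b in bad) in_cluster[b:hi[b]] <- TRUE
        hit <- snp[in_cluster]
        reason[rows[hit]] <- ifelse(is.na(reason[rows[hit]]),
                                    "snp_cluster", reason[rows[hit]])
      }
    }

    if (length(ind) && length(snp)) {
      ip <- pos[ind]
      near <- vapply(pos[snp], function(p) any(abs(ip - p) <= 5), logical(1))
      hit <- snp[near]
      reason[rows[hit]] <- ifelse(is.na(reason[rows[hit]]),
                                  "near_indel", reason[rows[hit]])
    }
  }

  .filter_report(sites, reason,
                 rule_order = c("indel_pair", "snp_cluster", "near_indel"))
}

#' Locus filters for the Euclidean-distance inputs
#'
#' Drops loci that cannot support the two-bulk frequency comparison:
#' indel-class records (only SNPs are scored), loci undetected (zero
#' depth) in either bulk, loci with evidence for more than two alleles
#' ("multiple mutations": more than two bases supported by at least
#' \code{min_alt_reads} reads in either bulk), and loci where both bulks
#' are homozygous for the same base (minor-base frequency below
#' \code{hom_threshold} in both bulks with an identical major base).
#' Removal reasons are assigned in that order.
#'
#' @param sites proximity-filtered \code{\link{bulk_sites}}.
#' @param min_alt_reads minimum reads for a base to count as an observed
#'   allele (default 2).
#' @param hom_threshold minor-base frequency below which a bulk is called
#'   homozygous (default 0.05).
#' @return a \code{filter_report} (see
#'   \code{\link{filter_variant_proximity}}); surviving sites are
#'   SNP-class with positive depth in both bulks.
#' @export
filter_ed_input <- function(sites, min_alt_reads = 2, hom_threshold = 0.05) {
  n <- nrow(sites)
  c1 <- as.matrix(sites[paste0(BASES, "_R01")])
  c2 <- as.matrix(sites[paste0(BASES, "_R02")])
  d1 <- rowSums(c1)
  d2 <- rowSums(c2)

  reason <- rep(NA_character_, n)
  take <- function(cond, tag) {
    hit <- cond & is.na(reason)
    reason[hit] <<- tag
  }
  take(sites$class == "indel", "indel")
  take(d1 == 0 | d2 == 0, "zero_depth")
  n_alleles1 <- rowSums(c1 >= min_alt_reads)
  n_alleles2 <- rowSums(c2 >= min_alt_reads)
  take(n_alleles1 > 2 | n_alleles2 > 2, "multiallelic")
  maj1 <- max.col(c1, ties.method = "first")
  maj2 <- max.col(c2, ties.method = "first")
  with_depth <- d1 > 0 & d2 > 0
  minor1 <- ifelse(with_depth, 1 - c1[cbind(seq_len(n), maj1)] / pmax(d1, 1), NA)
  minor2 <- ifelse(with_depth, 1 - c2[cbind(seq_len(n), maj2)] / pmax(d2, 1), NA)
  take(with_depth & maj1 == maj2 &
         minor1 < hom_threshold & minor2 < hom_threshold, "hom_consistent")

  .filter_report(sites, reason,
                 rule_order = c("indel", "zero_depth", "multiallelic",
                                "hom_consistent"))
}

.filter_report <- function(sites, reason, rule_order) {
  keep <- is.na(reason)
  removed <- data.frame(chrom = sites$chrom[!keep], pos = sites$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  counts <- table(factor(removed$reason, levels = rule_order))
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(sites, "chrom_lengths")
  structure(list(
    sites = out,
    removed = removed,
    counts = stats::setNames(as.integer(counts), rule_order),
    n_input = nrow(sites)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d sites in, %d removed, %d kept\n",
              x$n_input, nrow(x$removed), nrow(x$sites)))
  for (r in names(x$counts))
    cat(sprintf("  %-14s %d\n", r, x$counts[[r]]))
  invisible(x)
}

# summary suitable for JSON serialisation in the run manifest
filter_report_summary <- function(x) {
  list(n_input = x$n_input, n_removed = nrow(x$removed),
       n_kept = nrow(x$sites), removed_by_rule = as.list(x$counts))
}

#' Serialise a filter report
#'
#' Writes the per-site removal reasons as TSV and the per-rule summary
#' as JSON.
#'
#' @param report a \code{filter_report}.
#' @param tsv,json output paths (either may be \code{NULL} to skip).
#' @export
write_filter_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    writeLines(.provenance_line(), con)
    writeLines("chrom\tpos\treason", con)
    if (nrow(report$removed) > 0)
      writeLines(paste(report$removed$chrom, report$removed$pos,
                       report$removed$reason, sep = "\t"), con)
    close(con)
  }
  if (!is.null(json)) {
    jsonlite::write_json(filter_report_summary(report), json,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

.check_sorted <- function(sites) {
  if (nrow(sites) < 2) return(invisible(TRUE))
  o <- order(sites$chrom, sites$pos)
  if (any(o != seq_along(o)))
    stop("sites must be sorted by (chromosome, position)", call. = FALSE)
  invisible(TRUE)
}
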