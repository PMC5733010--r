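BASES <- c("A", "C", "G", "T")
COUNT_COLS <- c(paste0(BASES, "_R01"), paste0(BASES, "_R02"))

#' Two-bulk variant site table
#'
#' The package's internal representation of pooled variant calls: one row
#' per locus with 1-based position, REF/ALT alleles (ALT comma-separated
#' when multiallelic), variant class (\code{"SNP"} or \code{"indel"}),
#' and per-base read counts for the two bulk samples in columns
#' \code{A_R01 ... T_R01} and \code{A_R02 ... T_R02}. Optional columns
#' \code{dp_*}, \code{adr_*}, \code{ada_*} carry total and ref/alt
#' allelic depths when known (they are reconstructed from the base counts
#' otherwise).
#'
#' @param df data frame with at least \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{class} and the eight count columns.
#' @param chrom_lengths optional named vector, kept as an attribute and
#'   used for VCF contig headers and scan window layout.
#' @return the validated data frame with class \code{bulk_sites}.
#' @export
bulk_sites <- function(df, chrom_lengths = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "class", COUNT_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("bulk_sites: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) > 0) {
    if (any(df$pos < 1)) stop("bulk_sites: positions must be >= 1", call. = FALSE)
    cnt <- as.matrix(df[COUNT_COLS])
    if (any(cnt < 0) || any(cnt != round(cnt)))
      stop("bulk_sites: counts must be non-negative integers", call. = FALSE)
    if (!all(df$class %in% c("SNP", "indel")))
      stop("bulk_sites: class must be 'SNP' or 'indel'", call. = FALSE)
  }
  if (!is.null(chrom_lengths)) attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- unique(c("bulk_sites", class(df)))
  df
}

.site_depths <- function(sites) {
  list(r01 = rowSums(as.matrix(sites[paste0(BASES, "_R01")])),
       r02 = rowSums(as.matrix(sites[paste0(BASES, "_R02")])))
}

.provenance_line <- function() {
  sprintf("#bsascan=%s",
          as.character(utils::packageVersion("bsascan")))
}

#' Write two-bulk variant sites as VCF
#'
#' Emits VCF v4.2 with two samples, R01 (high/dominant bulk) and R02
#' (low/recessive bulk), and FORMAT fields \code{DP} (total depth),
#' \code{AD} (ref,alt allelic depths) and \code{BC} (per-base read counts
#' A,C,G,T — the inputs of the Euclidean-distance statistic, documented
#' in the header). Output is deterministic: the same sites produce
#' byte-identical files.
#'
#' @param sites a \code{\link{bulk_sites}} table.
#' @param path output file path (plain text).
#' @param sample_high,sample_low sample names for the two bulks.
#' @return \code{path}, invisibly.
#' @export
write_bulk_vcf <- function(sites, path, sample_high = "R01", sample_low = "R02") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=bsascan-%s", utils::packageVersion("bsascan")))
  cl <- attr(sites, "chrom_lengths")
  if (!is.null(cl)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(cl),
                          as.integer(cl)))
  }
  hdr <- c(hdr,
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=BC,Number=4,Type=Integer,Description="Read counts per base in A,C,G,T order">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_high, sample_low), collapse = "\t"))
  if (nrow(sites) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  d <- .site_depths(sites)
  dp1 <- if ("dp_R01" %in% names(sites)) sites$dp_R01 else d$r01
  dp2 <- if ("dp_R02" %in% names(sites)) sites$dp_R02 else d$r02
  ad <- function(which) {
    if (all(c(paste0("adr_", which), paste0("ada_", which)) %in% names(sites))) {
      paste(sites[[paste0("adr_", which)]], sites[[paste0("ada_", which)]],
            sep = ",")
    } else {
      # fall back to the base counts of the first ref/alt bases
      rb <- substr(sites$ref, 1, 1)
      ab <- substr(sub(",.*", "", sites$alt), 1, 1)
      cnt <- as.matrix(sites[paste0(BASES, "_", which)])
      paste(cnt[cbind(seq_len(nrow(sites)), match(rb, BASES))],
            cnt[cbind(seq_len(nrow(sites)), match(ab, BASES))], sep = ",")
    }
  }
  bc <- function(which) {
    cnt <- as.matrix(sites[paste0(BASES, "_", which)])
    apply(cnt, 1L, paste, collapse = ",")
  }
  body <- paste(sites$chrom, as.integer(sites$pos), ".", sites$ref, sites$alt, ".",
                "PASS", ".", "DP:AD:BC",
                paste(dp1, ad("R01"), bc("R01"), sep = ":"),
                paste(dp2, ad("R02"), bc("R02"), sep = ":"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Map comma-separated AD strings plus REF/ALT alleles onto per-base
# counts: each allele contributes its depth to its first base (alleles
# sharing a first base, e.g. deletion records, sum).
.ad_to_base_counts <- function(ad_str, ref, alt) {
  n <- length(ad_str)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  ads <- strsplit(ad_str, ",", fixed = TRUE)
  alts <- strsplit(alt, ",", fixed = TRUE)
  for (i in seq_len(n)) {
    alleles <- c(ref[i], alts[[i]])
    dep <- suppressWarnings(as.integer(ads[[i]]))
    dep[is.na(dep)] <- 0L
    b <- match(substr(alleles, 1, 1), BASES)
    for (k in seq_along(alleles)) {
      if (!is.na(b[k]) && k <= length(dep))
        out[i, b[k]] <- out[i, b[k]] + dep[k]
    }
  }
  out
}

#' Read a two-bulk VCF into a site table
#'
#' Parses a VCF (plain or bgzipped) holding the two bulk samples and
#' reconstructs per-base read counts: from the \code{BC} per-base
#' extension when present, otherwise from \code{AD} with each allele's
#' depth assigned to its first base (bases not among REF/ALT get count
#' zero, as callers report depths only for called alleles). Multiallelic
#' rows are kept as-is — rejecting them is the job of the downstream
#' locus filter. Records are returned sorted by (chromosome, position);
#' unsorted input is sorted with a warning.
#'
#' @param path VCF file.
#' @param sample_high,sample_low sample names of the high (dominant,
#'   default \code{"R01"}) and low (recessive, \code{"R02"}) bulks.
#' @return a \code{\link{bulk_sites}} table.
#' @export
read_bulk_vcf <- function(path, sample_high = "R01", sample_low = "R02") {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(sample_high, sample_low)) {
    if (!s %in% samples)
      stop(sprintf("sample '%s' not in VCF; available: %s", s,
                   paste(samples, collapse = ", ")), call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  n <- length(pos)

  fmt <- if (n > 0) strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]] else character()
  has_bc <- "BC" %in% fmt
  if (!has_bc && !"AD" %in% fmt)
    stop("VCF lacks the required AD (allelic depth) FORMAT field",
         call. = FALSE)

  get_counts <- function(sample) {
    if (has_bc) {
      bc <- vcfR::extract.gt(v, element = "BC")[, sample]
      m <- do.call(rbind, lapply(strsplit(bc, ",", fixed = TRUE), as.integer))
      colnames(m) <- BASES
      m
    } else {
      ad <- vcfR::extract.gt(v, element = "AD")[, sample]
      ad[is.na(ad)] <- "0"
      .ad_to_base_counts(ad, ref, alt)
    }
  }
  c1 <- get_counts(sample_high)
  c2 <- get_counts(sample_low)
  colnames(c1) <- paste0(BASES, "_R01")
  colnames(c2) <- paste0(BASES, "_R02")

  allele_lens <- vapply(strsplit(paste(ref, alt, sep = ","), ",", fixed = TRUE),
                        function(a) max(nchar(a[nzchar(a)])), integer(1))
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   class = ifelse(allele_lens != 1L, "indel", "SNP"),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(c1), as.data.frame(c2))

  if ("AD" %in% fmt) {
    ad1 <- strsplit(vcfR::extract.gt(v, element = "AD")[, sample_high], ",")
    ad2 <- strsplit(vcfR::extract.gt(v, element = "AD")[, sample_low], ",")
    first2 <- function(x) {
      y <- suppressWarnings(as.integer(x))
      c(y[1], if (length(y) >= 2) y[2] else 0L)
    }
    a1 <- vapply(ad1, first2, integer(2))
    a2 <- vapply(ad2, first2, integer(2))
    df$adr_R01 <- a1[1, ]; df$ada_R01 <- a1[2, ]
    df$adr_R02 <- a2[1, ]; df$ada_R02 <- a2[2, ]
  }
  if ("DP" %in% fmt) {
    df$dp_R01 <- as.integer(vcfR::extract.gt(v, element = "DP")[, sample_high])
    df$dp_R02 <- as.integer(vcfR::extract.gt(v, element = "DP")[, sample_low])
  }

  ord <- order(df$chrom, df$pos)
  if (is.unsorted(ord)) {
    warning("VCF records were not coordinate-sorted; sorting")
    df <- df[ord, , drop = FALSE]
  }
  rownames(df) <- NULL

  cl <- NULL
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", contig)))
    if (!any(is.na(lens))) cl <- stats::setNames(lens, ids)
  }
  bulk_sites(df, chrom_lengths = cl)
}

#' Write per-SNP Euclidean-distance scores as TSV
#'
#' One row per scored SNP with chromosome, position, raw ED, powered ED
#' and per-bulk depths, printed to 7 significant digits (lossless at the
#' precision downstream consumers read back).
#'
#' @param scores a \code{site_scores} table from \code{\link{ed_statistic}}.
#' @param path output TSV.
#' @export
write_ed_table <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(), con)
  writeLines(paste(c("chrom", "pos", "ed", "ed_pow", "dp_R01", "dp_R02"),
                   collapse = "\t"), con)
  if (nrow(scores) > 0) {
    writeLines(paste(scores$chrom, scores$pos,
                     sprintf("%.7g", scores$ed), sprintf("%.7g", scores$ed_pow),
                     scores$dp_R01, scores$dp_R02, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ed_table
#' @export
read_ed_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("site_scores", class(df))
  df
}

#' Write candidate regions as BED
#'
#' BED3+ with 0-based half-open coordinates (\code{start - 1, end}) plus
#' columns for the peak fitted value and the SNP count. Regions must be
#' sorted and non-overlapping within each chromosome.
#'
#' @param regions a \code{candidate_regions} table.
#' @param path output BED file.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) > 0) {
    for (ch in unique(regions$chrom)) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
        stop("write_regions_bed: overlapping regions on ", ch, call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(), con)
  if (nrow(regions) > 0) {
    writeLines(paste(regions$chrom, format(regions$start - 1, scientific = FALSE, trim = TRUE),
                     format(regions$end, scientific = FALSE, trim = TRUE),
                     sprintf("%.7g", regions$peak), regions$n_snps,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(candidate_regions(data.frame(
      chrom = character(), start = integer(), end = integer(),
      peak = numeric(), n_snps = integer())))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)) + 1L,
    end = as.integer(vapply(f, `[`, "", 3L)),
    peak = as.numeric(vapply(f, `[`, "", 4L)),
    n_snps = as.integer(vapply(f, `[`, "", 5L)),
    stringsAsFactors = FALSE)
  candidate_regions(df)
}
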