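#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation and keeps gene-level features as a plain
#' table used by the region-annotation step.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default \code{"gene"}).
#' @return data frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive) and \code{strand}.
#' @export
read_gene_gff <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Read a gene-to-pathway membership table
#'
#' Two-column TSV (\code{gene_id}, \code{pathway_id}); many-to-many.
#' @param path TSV file.
#' @export
read_pathway_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "pathway_id")
  if (!all(need %in% names(df)))
    stop("pathway table must have columns gene_id and pathway_id", call. = FALSE)
  df
}

#' Read a differential-expression gene table
#'
#' TSV with columns \code{gene_id}, \code{log2fc}, \code{adjusted_p} and
#' optionally \code{contrast} (e.g. a leaf position). Malformed numeric
#' fields are reported with their line number.
#' @param path TSV file.
#' @export
read_deg_table <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "log2fc", "adjusted_p")
  if (!all(need %in% names(raw)))
    stop("DEG table must have columns gene_id, log2fc, adjusted_p",
         call. = FALSE)
  for (col in c("log2fc", "adjusted_p")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed DEG table: non-numeric '%s' at line %d",
                   col, bad[1] + 1L), call. = FALSE)
    raw[[col]] <- v
  }
  raw
}

#' Genes overlapping candidate regions
#'
#' A gene belongs to a region iff its interval overlaps the region by at
#' least one base (overlap, not containment). Coordinates are 1-based
#' inclusive on both sides. Overlap is computed with IRanges.
#'
#' @param regions a \code{candidate_regions} table (or any data frame
#'   with chrom/start/end).
#' @param genes gene table as from \code{\link{read_gene_gff}}.
#' @return named list, one character vector of gene ids per region
#'   (names \code{"chrom:start-end"}), ordered by gene position.
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0) return(stats::setNames(list(), character()))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(rg, gg)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    j <- S4Vectors_subjectHits(hits)[S4Vectors_queryHits(hits) == i]
    j <- j[order(genes$start[j])]
    genes$gene_id[j]
  })
  names(out) <- sprintf("%s:%s-%s", regions$chrom,
                        format(regions$start, scientific = FALSE, trim = TRUE),
                        format(regions$end, scientific = FALSE, trim = TRUE))
  out
}

# thin indirection so the IRanges accessors are easy to stub in tests
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' Pathway enrichment of region genes
#'
#' For every pathway represented among the region genes, tests
#' over-representation relative to the whole-genome background with a
#' one-sided Fisher's exact test on the 2x2 table (in-region x
#' in-pathway). No multiple-testing correction is applied by default,
#' matching the raw \code{P < alpha} significance criterion; set
#' \code{adjust = TRUE} for Benjamini-Hochberg.
#'
#' @param region_genes character vector of gene ids in the candidate
#'   region(s); must be a subset of \code{all_genes}.
#' @param all_genes character vector: the genome-wide background.
#' @param pathway_table data frame (gene_id, pathway_id).
#' @param alpha significance level (default 0.05).
#' @param adjust apply Benjamini-Hochberg to the P-values (default FALSE).
#' @return data frame sorted by P: pathway_id, the 2x2 counts
#'   (\code{k} region genes in pathway, \code{n_region},
#'   \code{K} background genes in pathway, \code{N} background size),
#'   sample odds ratio, one-sided \code{p_value} and \code{significant}.
#' @examples
#' pw <- data.frame(gene_id = paste0("g", 1:10), pathway_id = "P")
#' pathway_enrichment(paste0("g", c(1:4, 90:95)), paste0("g", 1:100), pw)
#' @export
pathway_enrichment <- function(region_genes, all_genes, pathway_table,
                               alpha = 0.05, adjust = FALSE) {
  region_genes <- unique(region_genes)
  all_genes <- unique(all_genes)
  missing <- setdiff(region_genes, all_genes)
  if (length(missing))
    stop("region genes absent from the background set: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  n <- length(region_genes)
  N <- length(all_genes)
  pw <- pathway_table[pathway_table$gene_id %in% all_genes, , drop = FALSE]
  pw <- unique(pw[c("gene_id", "pathway_id")])
  by_pw <- split(pw$gene_id, pw$pathway_id)

  rows <- lapply(names(by_pw), function(p) {
    members <- by_pw[[p]]
    k <- sum(region_genes %in% members)
    if (k == 0) return(NULL)
    K <- length(members)
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
    pval <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
    data.frame(pathway_id = p, k = k, n_region = n, K = K, N = N,
               odds_ratio = or, p_value = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(), k = integer(),
                      n_region = integer(), K = integer(), N = integer(),
                      odds_ratio = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  if (adjust) out$p_value_adj <- stats::p.adjust(out$p_value, "BH")
  crit <- if (adjust) out$p_value_adj else out$p_value
  out$significant <- crit < alpha
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference region genes with differential expression
#'
#' Nominates candidate genes: region genes whose adjusted P is below
#' \code{alpha} in at least one supplied contrast, annotated with the
#' significant contrasts. Region genes absent from the DEG table are
#' tallied as untested rather than treated as non-significant.
#'
#' @param region_genes character vector of gene ids.
#' @param deg_table data frame from \code{\link{read_deg_table}}.
#' @param alpha adjusted-P cut for calling a gene differentially
#'   expressed (default 0.05).
#' @return list: \code{$candidates} (gene_id, contrasts, min adjusted P,
#'   log2fc at that minimum), \code{$untested} gene ids missing from the
#'   table, and \code{$n_tested}.
#' @export
cross_reference_degs <- function(region_genes, deg_table, alpha = 0.05) {
  region_genes <- unique(region_genes)
  if (!"contrast" %in% names(deg_table)) deg_table$contrast <- "all"
  tab <- deg_table[deg_table$gene_id %in% region_genes, , drop = FALSE]
  untested <- setdiff(region_genes, tab$gene_id)
  sig <- tab[!is.na(tab$adjusted_p) & tab$adjusted_p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    cand <- data.frame(gene_id = character(), contrasts = character(),
                       min_adjusted_p = numeric(), log2fc = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    cand <- do.call(rbind, lapply(split(sig, sig$gene_id), function(g) {
      i <- which.min(g$adjusted_p)
      data.frame(gene_id = g$gene_id[1],
                 contrasts = paste(sort(unique(g$contrast)), collapse = ","),
                 min_adjusted_p = g$adjusted_p[i], log2fc = g$log2fc[i],
                 stringsAsFactors = FALSE)
    }))
    cand <- cand[order(cand$min_adjusted_p, cand$gene_id), , drop = FALSE]
    rownames(cand) <- NULL
  }
  list(candidates = cand, untested = untested,
       n_tested = length(region_genes) - length(untested))
}
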