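#' Generate annotation fixtures for the synthetic genome
#'
#' Builds the three annotation inputs the region-annotation stage
#' consumes, matched to a simulated genome: non-overlapping gene models
#' tiled along each chromosome (GFF3), a gene-to-pathway membership
#' table in which one configurable pathway is enriched inside a chosen
#' interval, and a differential-expression table flagging a configurable
#' subset of genes. Output is fully determined by \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}} (chromosome lengths + seed).
#' @param out_dir directory to write \code{genes.gff3},
#'   \code{pathways.tsv} and \code{degs.tsv}; \code{NULL} skips writing.
#' @param n_genes total genes to tile across the genome.
#' @param gene_length gene span in bp.
#' @param n_pathways background pathways in addition to the planted one.
#' @param planted list describing the enrichment to plant:
#'   \code{pathway} id, \code{chrom}/\code{start}/\code{end} of the
#'   enriched interval, \code{n_in_region} member genes inside it and
#'   \code{n_total} members genome-wide. \code{NULL} plants nothing.
#' @param deg_in_region,deg_background genes flagged differentially
#'   expressed (adjusted P < 0.05) inside the planted interval and
#'   elsewhere.
#' @param deg_coverage fraction of genes present in the DEG table at all
#'   (absent genes exercise the "untested" path downstream).
#' @param contrasts contrast labels for the DEG table (e.g. leaf
#'   positions); each covered gene gets one row per contrast.
#' @return list with data frames \code{genes}, \code{pathways},
#'   \code{degs} and, when written, \code{paths}.
#' @export
generate_annotation_fixture <- function(config, out_dir = NULL,
                                        n_genes = 100, gene_length = 2000,
                                        n_pathways = 5,
                                        planted = list(pathway = "pw_planted",
                                                       chrom = NULL,
                                                       start = NULL, end = NULL,
                                                       n_in_region = 4,
                                                       n_total = 10),
                                        deg_in_region = 2, deg_background = 5,
                                        deg_coverage = 0.9,
                                        contrasts = c("apical", "middle", "basal")) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  cl <- config$chrom_lengths

  genes <- .tile_genes(cl, n_genes, gene_length)

  if (!is.null(planted)) {
    if (is.null(planted$chrom)) {
      # default planted interval: centred on the causal locus (or the
      # middle of the first chromosome for a null genome)
      ch <- if (!is.na(config$causal_chrom)) config$causal_chrom else names(cl)[1]
      mid <- if (!is.na(config$causal_chrom)) config$causal_pos else cl[[ch]] / 2
      planted$chrom <- ch
      planted$start <- max(1, mid - 2.5e5)
      planted$end <- min(cl[[ch]], mid + 2.5e5)
    }
    if (!planted$chrom %in% names(cl) || planted$start < 1 ||
        planted$end > cl[[planted$chrom]] || planted$start > planted$end)
      stop("planted enrichment interval lies outside the declared genome",
           call. = FALSE)
  }

  pathways <- .plant_pathways(genes, n_pathways, planted)
  degs <- .make_degs(genes, planted, deg_in_region, deg_background,
                     deg_coverage, contrasts)

  out <- list(genes = genes, pathways = pathways, degs = degs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff = file.path(out_dir, "genes.gff3"),
                  pathways = file.path(out_dir, "pathways.tsv"),
                  degs = file.path(out_dir, "degs.tsv"))
    .write_gff3(genes, cl, paths$gff)
    utils::write.table(pathways, paths$pathways, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(degs, paths$degs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

# evenly tiled, guaranteed non-overlapping gene intervals
.tile_genes <- function(chrom_lengths, n_genes, gene_length) {
  if (n_genes == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  share <- chrom_lengths / sum(chrom_lengths)
  counts <- diff(round(cumsum(c(0, share)) * n_genes))
  rows <- mapply(function(chrom, len, k) {
    if (k == 0) return(NULL)
    span <- len / k
    glen <- min(gene_length, floor(span) - 1)
    start <- floor((seq_len(k) - 1) * span + span / 2 - glen / 2) + 1L
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + glen - 1L),
               stringsAsFactors = FALSE)
  }, names(chrom_lengths), chrom_lengths, counts, SIMPLIFY = FALSE)
  df <- do.call(rbind, rows)
  df$gene_id <- sprintf("gene%04d", seq_len(nrow(df)))
  df$strand <- rep_len(c("+", "-"), nrow(df))
  rownames(df) <- NULL
  df[c("gene_id", "chrom", "start", "end", "strand")]
}

.plant_pathways <- function(genes, n_pathways, planted) {
  rows <- list()
  if (!is.null(planted) && nrow(genes) > 0) {
    in_region <- genes$gene_id[genes$chrom == planted$chrom &
                                 genes$end >= planted$start &
                                 genes$start <= planted$end]
    out_region <- setdiff(genes$gene_id, in_region)
    k_in <- min(planted$n_in_region, length(in_region))
    k_out <- min(planted$n_total - k_in, length(out_region))
    members <- c(sample(in_region, k_in), sample(out_region, k_out))
    if (length(members))
      rows[[1]] <- data.frame(gene_id = members, pathway_id = planted$pathway,
                              stringsAsFactors = FALSE)
  }
  if (n_pathways > 0 && nrow(genes) > 0) {
    for (i in seq_len(n_pathways)) {
      k <- max(1L, round(nrow(genes) / 10))
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sample(genes$gene_id, k),
        pathway_id = sprintf("pw%02d", i), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), pathway_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.make_degs <- function(genes, planted, deg_in_region, deg_background,
                       deg_coverage, contrasts) {
  empty <- data.frame(gene_id = character(), contrast = character(),
                      log2fc = numeric(), adjusted_p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(empty)
  in_region <- if (!is.null(planted)) {
    genes$gene_id[genes$chrom == planted$chrom &
                    genes$end >= planted$start & genes$start <= planted$end]
  } else character()
  out_region <- setdiff(genes$gene_id, in_region)
  de <- c(sample(in_region, min(deg_in_region, length(in_region))),
          sample(out_region, min(deg_background, length(out_region))))
  covered <- union(de, sample(genes$gene_id,
                              round(deg_coverage * nrow(genes))))
  rows <- lapply(contrasts, function(ct) {
    p <- ifelse(covered %in% de,
                stats::runif(length(covered), 1e-6, 0.04),
                stats::runif(length(covered), 0.2, 1))
    data.frame(gene_id = covered, contrast = ct,
               log2fc = round(stats::rnorm(length(covered),
                                           ifelse(covered %in% de, 2, 0), 0.5), 3),
               adjusted_p = signif(p, 4), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$contrast), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.write_gff3 <- function(genes, chrom_lengths, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = rep("gene", nrow(genes)),
    source = rep("bsascan_sim", nrow(genes)),
    ID = genes$gene_id,
    Name = genes$gene_id)
  if (length(chrom_lengths)) {
    lv <- GenomeInfoDb::seqlevels(gr)
    GenomeInfoDb::seqlengths(gr) <-
      stats::setNames(as.integer(chrom_lengths)[match(lv, names(chrom_lengths))],
                      lv)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
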