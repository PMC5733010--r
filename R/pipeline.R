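#' Default run configuration
#'
#' Assembles the full pipeline configuration with every analysis default
#' at its standard value (power 5, 1-Mb window, 3 SD above the median,
#' alpha 0.05, 25 plants per bulk, mean depths 23/28). Values supplied in
#' \code{...} override defaults; a YAML file with the same keys can be
#' loaded with \code{\link{read_run_config}}.
#'
#' @param mode one of \code{"simulate"}, \code{"scan"},
#'   \code{"annotate"}, \code{"full"}.
#' @param out_dir output directory.
#' @param ... overrides: \code{vcf}, \code{gff}, \code{pathways},
#'   \code{degs}, \code{sample_high}, \code{sample_low}, \code{power},
#'   \code{window}, \code{step}, \code{min_snps}, \code{n_sd},
#'   \code{alpha}, \code{seed}, \code{mask}, \code{sim} (a
#'   \code{\link{sim_config}} or list of its arguments),
#'   \code{n_population}.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(mode = c("full", "simulate", "scan", "annotate"),
                       out_dir = "bsascan_out", ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, out_dir = out_dir,
    vcf = NULL, gff = NULL, pathways = NULL, degs = NULL,
    regions_bed = NULL,
    sample_high = "R01", sample_low = "R02",
    power = 5, window = 1e6, step = NULL, min_snps = 10, n_sd = 3,
    gap_tolerance = 0, min_alt_reads = 2, hom_threshold = 0.05,
    alpha = 0.05, mask = NULL, seed = 1L,
    sim = NULL, n_population = 125)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown run_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (is.null(cfg$step)) cfg$step <- cfg$window / 100
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror \code{\link{run_config}}
#'   arguments (with \code{sim} as a nested mapping of
#'   \code{\link{sim_config}} arguments).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mode <- y$mode %||% "full"
  out_dir <- y$out_dir %||% "bsascan_out"
  y$mode <- NULL; y$out_dir <- NULL
  if (!is.null(y$sim) && !is.null(y$sim$chrom_lengths))
    y$sim$chrom_lengths <- unlist(y$sim$chrom_lengths)
  do.call(run_config, c(list(mode = mode, out_dir = out_dir), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_sim_config <- function(config) {
  s <- config$sim
  if (inherits(s, "sim_config")) return(s)
  args <- if (is.list(s)) s else list()
  if (is.null(args$seed)) args$seed <- config$seed
  do.call(sim_config, args)
}

.stage_files <- function(paths) {
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the staged BSA-seq pipeline
#'
#' Orchestrates simulate -> read -> filter -> scan -> annotate as one
#' reproducible run. Modes: \code{"simulate"} writes the synthetic VCF
#' and annotation fixtures; \code{"scan"} reads a VCF, filters, scans
#' and writes the ED table, fitted track, regions BED and a per-
#' chromosome plot; \code{"annotate"} intersects regions with genes,
#' tests pathway enrichment and cross-references DEGs; \code{"full"}
#' chains all three. A JSON manifest with the config echo, per-stage
#' output checksums, filter removal counts, SNP count, threshold and
#' region calls is written last; identical config + seed reproduces
#' byte-identical primary outputs (the plot is exempt).
#'
#' @param config a \code{\link{run_config}}, a YAML path, or a list of
#'   \code{run_config} arguments.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    tool = sprintf("bsascan %s", utils::packageVersion("bsascan")),
    mode = config$mode,
    config = config[!vapply(config, is.null, logical(1))],
    stages = list())
  scan <- NULL
  sites <- NULL

  do_sim <- config$mode %in% c("simulate", "full")
  do_scan <- config$mode %in% c("scan", "full")
  do_annot <- config$mode %in% c("annotate", "full")

  if (do_sim) {
    scfg <- .as_sim_config(config)
    vcf <- file.path(config$out_dir, "simulated.vcf")
    sim <- simulate_bsa(scfg, n_population = config$n_population, vcf = vcf)
    fix <- generate_annotation_fixture(scfg, out_dir = config$out_dir)
    sites <- sim$sites
    config$vcf <- vcf
    config$gff <- fix$paths$gff
    config$pathways <- fix$paths$pathways
    config$degs <- fix$paths$degs
    manifest$stages$simulate <- list(
      n_sites = nrow(sim$sites), n_genes = nrow(fix$genes),
      outputs = .stage_files(c(vcf, fix$paths)))
  }

  if (do_scan) {
    if (is.null(config$vcf) || !file.exists(config$vcf))
      stop("scan stage: VCF not found: ",
           config$vcf %||% "(not set)", call. = FALSE)
    if (is.null(sites))
      sites <- read_bulk_vcf(config$vcf, config$sample_high, config$sample_low)
    scan <- ed_scan(sites, power = config$power, window = config$window,
                    step = config$step, min_snps = config$min_snps,
                    n_sd = config$n_sd, gap_tolerance = config$gap_tolerance,
                    mask = config$mask, min_alt_reads = config$min_alt_reads,
                    hom_threshold = config$hom_threshold)
    ed_tsv <- file.path(config$out_dir, "ed_scores.tsv")
    track_tsv <- file.path(config$out_dir, "fitted_track.tsv")
    bed <- file.path(config$out_dir, "candidate_regions.bed")
    filt_tsv <- file.path(config$out_dir, "filtered_sites.tsv")
    filt_json <- file.path(config$out_dir, "filter_summary.json")
    write_ed_table(scan$scores, ed_tsv)
    utils::write.table(scan$track, track_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_regions_bed(scan$regions, bed)
    both <- rbind(scan$filters$proximity$removed, scan$filters$ed_input$removed)
    write_filter_report(list(removed = both,
                             counts = c(scan$filters$proximity$counts,
                                        scan$filters$ed_input$counts),
                             n_input = scan$filters$proximity$n_input,
                             sites = scan$scores),
                        tsv = filt_tsv, json = filt_json)
    plot_png <- file.path(config$out_dir, "ed_scan.png")
    grDevices::png(plot_png, width = 900,
                   height = 280 * length(unique(scan$track$chrom)))
    plot(scan)
    grDevices::dev.off()
    config$regions_bed <- bed
    manifest$stages$scan <- list(
      n_input_sites = scan$filters$proximity$n_input,
      removed_proximity = as.list(scan$filters$proximity$counts),
      removed_locus = as.list(scan$filters$ed_input$counts),
      n_snps_scored = nrow(scan$scores),
      threshold = list(median = scan$threshold$median, sd = scan$threshold$sd,
                       tau = scan$threshold$tau),
      n_regions = nrow(scan$regions),
      regions = scan$regions,
      outputs = .stage_files(c(ed_tsv, track_tsv, bed, filt_tsv, filt_json)))
  }

  if (do_annot) {
    for (f in c("gff", "pathways", "regions_bed")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("annotate stage: required input '", f, "' missing",
             call. = FALSE)
    }
    regions <- if (!is.null(scan)) scan$regions else read_regions_bed(config$regions_bed)
    genes <- read_gene_gff(config$gff)
    pw <- read_pathway_table(config$pathways)
    by_region <- genes_in_regions(regions, genes)
    region_genes <- unique(unlist(by_region))
    enr <- pathway_enrichment(region_genes, genes$gene_id, pw,
                              alpha = config$alpha)
    enr_tsv <- file.path(config$out_dir, "pathway_enrichment.tsv")
    utils::write.table(enr, enr_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(enr_tsv)
    cand <- NULL
    if (!is.null(config$degs) && file.exists(config$degs)) {
      cand <- cross_reference_degs(region_genes, read_deg_table(config$degs),
                                   alpha = config$alpha)
      cand_tsv <- file.path(config$out_dir, "candidate_genes.tsv")
      utils::write.table(cand$candidates, cand_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, cand_tsv)
    }
    manifest$stages$annotate <- list(
      n_regions = nrow(regions),
      n_region_genes = length(region_genes),
      genes_per_region = lapply(by_region, length),
      n_pathways_tested = nrow(enr),
      top_pathway = if (nrow(enr)) enr$pathway_id[1] else NA,
      n_candidate_genes = if (!is.null(cand)) nrow(cand$candidates) else NA,
      n_untested = if (!is.null(cand)) length(cand$untested) else NA,
      outputs = .stage_files(outs))
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  invisible(manifest)
}
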