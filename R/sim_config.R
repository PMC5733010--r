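#' Configuration for the synthetic two-bulk cross
#'
#' Describes the full generative model behind the synthetic BSA-seq data:
#' the genome (chromosome lengths and marker spacing), the segregating
#' causal locus and its dominance model, the bulk design, and the pooled
#' sequencing model (per-bulk mean depth, per-base error rate, indel and
#' clustered-artifact rates).
#'
#' The defaults describe a selfed population segregating ~3:1 for a
#' dominant trait, with two 25-plant bulks sequenced at mean depths of 23x
#' (dominant-phenotype bulk, sample \code{R01}) and 28x
#' (recessive-phenotype bulk, sample \code{R02}).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param marker_spacing distance between adjacent segregating markers, bp.
#' @param causal_chrom,causal_pos location of the single causal locus.
#'   \code{causal_chrom = NA} simulates a null genome with no causal locus.
#' @param dominance \code{"dominant"} (default; one copy of the reference
#'   allele gives the dominant phenotype) or \code{"additive_threshold"}
#'   (phenotype determined by reference-allele dosage \code{>=}
#'   \code{pheno_threshold}).
#' @param pheno_threshold dosage threshold for \code{"additive_threshold"}.
#' @param n_per_bulk plants per bulk.
#' @param depth_high,depth_low mean sequencing depth of the
#'   dominant-phenotype (R01) and recessive-phenotype (R02) bulk.
#' @param error_rate per-base sequencing error probability; an erroneous
#'   read reports one of the three other bases uniformly.
#' @param indel_fraction fraction of markers emitted as indel-class records.
#' @param cluster_rate probability that a marker spawns a dense artifact
#'   cluster (>= 3 SNPs within a 5-bp window, or an indel pair < 10 bp
#'   apart), used to exercise the proximity filters.
#' @param cm_per_mb recombination rate used to convert physical to map
#'   distance (Haldane map function).
#' @param mispheno_rate probability that a plant's phenotype is recorded
#'   incorrectly before bulk selection.
#' @param seed integer seed; identical \code{(config, seed)} produces
#'   byte-identical simulated output.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chr1 = 5e6), causal_pos = 2.5e6)
#' cfg$n_per_bulk
#' @export
sim_config <- function(chrom_lengths = c(A06 = 30e6),
                       marker_spacing = 3000,
                       causal_chrom = names(chrom_lengths)[1],
                       causal_pos = floor(chrom_lengths[[1]] / 2),
                       dominance = c("dominant", "additive_threshold"),
                       pheno_threshold = 1,
                       n_per_bulk = 25,
                       depth_high = 23,
                       depth_low = 28,
                       error_rate = 0.001,
                       indel_fraction = 0.05,
                       cluster_rate = 0.01,
                       cm_per_mb = 4,
                       mispheno_rate = 0,
                       seed = 1L) {
  dominance <- match.arg(dominance)
  cfg <- structure(list(
    chrom_lengths = chrom_lengths,
    marker_spacing = marker_spacing,
    causal_chrom = causal_chrom,
    causal_pos = causal_pos,
    dominance = dominance,
    pheno_threshold = pheno_threshold,
    n_per_bulk = n_per_bulk,
    depth_high = depth_high,
    depth_low = depth_low,
    error_rate = error_rate,
    indel_fraction = indel_fraction,
    cluster_rate = cluster_rate,
    cm_per_mb = cm_per_mb,
    mispheno_rate = mispheno_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config: field '%s' %s", field, msg), call. = FALSE)
  }
  cl <- cfg$chrom_lengths
  if (length(cl) < 1 || any(!is.finite(cl)) || any(cl < 1))
    fail("chrom_lengths", "must be positive and finite")
  if (is.null(names(cl)) || any(!nzchar(names(cl))) || anyDuplicated(names(cl)))
    fail("chrom_lengths", "must have unique non-empty names")
  if (!is.finite(cfg$marker_spacing) || cfg$marker_spacing < 1)
    fail("marker_spacing", "must be >= 1 bp")
  if (!is.na(cfg$causal_chrom)) {
    if (!cfg$causal_chrom %in% names(cl))
      fail("causal_chrom", "is not a declared chromosome")
    if (!is.finite(cfg$causal_pos) || cfg$causal_pos < 1 ||
        cfg$causal_pos > cl[[cfg$causal_chrom]])
      fail("causal_pos", "lies outside [1, chromosome length]")
  }
  if (!is.finite(cfg$n_per_bulk) || cfg$n_per_bulk < 1)
    fail("n_per_bulk", "must be >= 1")
  if (!is.finite(cfg$depth_high) || cfg$depth_high < 0)
    fail("depth_high", "must be >= 0")
  if (!is.finite(cfg$depth_low) || cfg$depth_low < 0)
    fail("depth_low", "must be >= 0")
  if (cfg$depth_high <= 0 && cfg$depth_low <= 0)
    fail("depth_high/depth_low", "mean depth must be > 0 for at least one bulk")
  if (!is.finite(cfg$error_rate) || cfg$error_rate < 0 || cfg$error_rate >= 0.25)
    fail("error_rate", "must satisfy 0 <= error_rate < 0.25")
  if (cfg$indel_fraction < 0 || cfg$indel_fraction > 1)
    fail("indel_fraction", "must be in [0, 1]")
  if (cfg$cluster_rate < 0 || cfg$cluster_rate > 1)
    fail("cluster_rate", "must be in [0, 1]")
  if (!is.finite(cfg$cm_per_mb) || cfg$cm_per_mb < 0)
    fail("cm_per_mb", "must be >= 0")
  if (cfg$mispheno_rate < 0 || cfg$mispheno_rate >= 1)
    fail("mispheno_rate", "must be in [0, 1)")
  if (!is.finite(cfg$seed)) fail("seed", "must be a finite integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-bulk BSA-seq simulation config\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total, markers every %d bp\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              as.integer(x$marker_spacing)))
  if (is.na(x$causal_chrom)) {
    cat("  causal locus: none (null genome)\n")
  } else {
    cat(sprintf("  causal locus: %s:%s (%s)\n", x$causal_chrom,
                format(x$causal_pos, big.mark = ","), x$dominance))
  }
  cat(sprintf("  bulks: %d plants each; mean depth %g (R01) / %g (R02); error rate %g\n",
              x$n_per_bulk, x$depth_high, x$depth_low, x$error_rate))
  cat(sprintf("  map: Haldane, %g cM/Mb; indel fraction %g; cluster rate %g; seed %d\n",
              x$cm_per_mb, x$indel_fraction, x$cluster_rate, x$seed))
  invisible(x)
}

# Marker map implied by a config: one row per segregating marker, the
# causal position inserted if it does not fall on the regular grid.
marker_map <- function(cfg) {
  maps <- lapply(names(cfg$chrom_lengths), function(chrom) {
    len <- cfg$chrom_lengths[[chrom]]
    pos <- as.integer(seq(cfg$marker_spacing, len, by = cfg$marker_spacing))
    if (!is.na(cfg$causal_chrom) && chrom == cfg$causal_chrom &&
        !(cfg$causal_pos %in% pos)) {
      pos <- sort(c(pos, as.integer(cfg$causal_pos)))
    }
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$is_causal <- !is.na(cfg$causal_chrom) &
    map$chrom == cfg$causal_chrom & map$pos == cfg$causal_pos
  map
}
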