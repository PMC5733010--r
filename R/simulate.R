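#' Simulate a selfed segregating population
#'
#' Generates \code{n} diploid plants as selfed progeny of a single parent
#' that is heterozygous at every marker and at the causal locus (an
#' F2-like design). Each plant is formed from two independent gametes;
#' within a gamete, recombination occurs between adjacent loci with
#' probability \code{r = 0.5 * (1 - exp(-2 d))} (Haldane's map function),
#' where \code{d} is the map distance in Morgans implied by the physical
#' distance and \code{cm_per_mb}. Chromosomes assort independently.
#' Single-locus genotype frequencies are 1:2:1 in expectation.
#'
#' Alleles are coded 0 (reference, dominant at the causal locus) and
#' 1 (alternate, recessive).
#'
#' @param config a \code{\link{sim_config}}.
#' @param n number of plants to simulate.
#' @return an object of class \code{bsa_population}: the marker map plus
#'   two \code{n x markers} haplotype matrices.
#' @examples
#' pop <- simulate_population(sim_config(chrom_lengths = c(c1 = 1e6),
#'                                       marker_spacing = 1e5), n = 10)
#' dim(pop$hap1)
#' @export
simulate_population <- function(config, n) {
  validate_sim_config(config)
  if (!is.finite(n) || n < 1) {
    stop("invalid sim_config: field 'n' (population size) must be >= 1",
         call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(config$seed)
  map <- marker_map(config)
  n_gam <- 2L * n

  haps <- matrix(0L, nrow = n_gam, ncol = nrow(map))
  for (chrom in names(config$chrom_lengths)) {
    idx <- which(map$chrom == chrom)
    m <- length(idx)
    if (m == 0L) next
    start <- stats::rbinom(n_gam, 1L, 0.5)
    if (m == 1L) {
      haps[, idx] <- start
      next
    }
    d_morgan <- diff(map$pos[idx]) / 1e6 * config$cm_per_mb / 100
    r <- 0.5 * (1 - exp(-2 * d_morgan))
    # crossover indicators per interval (rows) and gamete (columns);
    # cumulative parity gives the haplotype origin at each marker
    xo <- matrix(stats::rbinom((m - 1L) * n_gam, 1L, rep(r, times = n_gam)),
                 nrow = m - 1L, ncol = n_gam)
    parity <- rbind(0L, apply(xo, 2L, cumsum))
    haps[, idx] <- t((parity + rep(start, each = m)) %% 2L)
  }

  structure(list(
    map = map,
    hap1 = haps[seq_len(n) * 2L - 1L, , drop = FALSE],
    hap2 = haps[seq_len(n) * 2L, , drop = FALSE],
    config = config
  ), class = "bsa_population")
}

#' @export
print.bsa_population <- function(x, ...) {
  cat(sprintf("Simulated selfed population: %d plants, %d markers on %d chromosome(s)\n",
              nrow(x$hap1), nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

# Alternate-allele dosage (0/1/2) of every plant at one marker index.
.dosage_at <- function(pop, j) pop$hap1[, j] + pop$hap2[, j]

# Phenotype of every plant under the config's dominance model.
# TRUE = dominant phenotype (reference-allele carrier), FALSE = recessive.
.phenotype <- function(pop, config) {
  if (is.na(config$causal_chrom)) {
    # null genome: phenotypes mimic a 3:1 split with no genetic basis
    stats::rbinom(nrow(pop$hap1), 1L, 0.75) == 1L
  } else {
    j <- which(pop$map$is_causal)
    ref_dosage <- 2L - .dosage_at(pop, j)
    thr <- if (config$dominance == "dominant") 1L else config$pheno_threshold
    ref_dosage >= thr
  }
}

#' Select the two phenotype bulks
#'
#' Draws the high (dominant-phenotype, sample R01) and low
#' (recessive-phenotype, sample R02) bulks from a simulated population,
#' each of exactly \code{config$n_per_bulk} plants, sampled without
#' replacement. Under the default dominance model the low bulk contains
#' only plants homozygous for the recessive allele at the causal locus,
#' while the high bulk mixes homozygous and heterozygous carriers
#' (1 AA : 2 Aa in expectation), so the expected recessive-allele
#' frequency in the high bulk is 1/3.
#'
#' A nonzero \code{mispheno_rate} flips recorded phenotypes before
#' selection, contaminating the bulks.
#'
#' @param population a \code{bsa_population}.
#' @param config the \code{\link{sim_config}} used to build it.
#' @return a list of class \code{bsa_bulks} with integer plant indices
#'   \code{$high} and \code{$low}.
#' @export
select_bulks <- function(population, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  pheno <- .phenotype(population, config)
  if (config$mispheno_rate > 0) {
    flip <- stats::runif(length(pheno)) < config$mispheno_rate
    pheno[flip] <- !pheno[flip]
  }
  dom <- which(pheno)
  rec <- which(!pheno)
  k <- config$n_per_bulk
  if (length(dom) < k || length(rec) < k) {
    stop(sprintf(paste0(
      "cannot fill %d-plant bulks: %d dominant and %d recessive plants ",
      "available; simulate a larger population"),
      k, length(dom), length(rec)), call. = FALSE)
  }
  structure(list(
    high = sort(sample(dom, k)),
    low = sort(sample(rec, k))
  ), class = "bsa_bulks")
}

# Redistribute sequencing errors: take `err` reads away from base `from`
# and scatter them uniformly over the other three bases. Vectorised over
# sites; only sites with err > 0 need the multinomial draw.
.scatter_errors <- function(counts, from, err) {
  hit <- which(err > 0L)
  for (i in hit) {
    others <- setdiff(1:4, from[i])
    add <- stats::rmultinom(1L, err[i], rep(1 / 3, 3))[, 1L]
    counts[i, from[i]] <- counts[i, from[i]] - err[i]
    counts[i, others] <- counts[i, others] + add
  }
  counts
}

# Pooled read counts for one bulk at every marker.
# freq: alternate-allele frequency among the bulk's haplotypes.
.pool_reads <- function(freq, mean_depth, ref_b, alt_b, is_snp, error_rate) {
  m <- length(freq)
  depth <- stats::rpois(m, mean_depth)
  alt_reads <- stats::rbinom(m, depth, freq)
  ref_reads <- depth - alt_reads
  counts <- matrix(0L, nrow = m, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  # indel-class records keep all reads on the first reference base; the
  # per-base vector is only meaningful for SNPs (indels are filtered
  # before scoring)
  counts[cbind(seq_len(m), ref_b)] <- ref_reads
  idx <- cbind(seq_len(m), ifelse(is_snp, alt_b, ref_b))
  counts[idx] <- counts[idx] + alt_reads
  if (error_rate > 0) {
    snp <- which(is_snp)
    e_ref <- integer(m); e_alt <- integer(m)
    e_ref[snp] <- stats::rbinom(length(snp), ref_reads[snp], error_rate)
    e_alt[snp] <- stats::rbinom(length(snp), alt_reads[snp], error_rate)
    counts <- .scatter_errors(counts, ref_b, e_ref)
    counts <- .scatter_errors(counts, alt_b, e_alt)
    ref_reads <- ref_reads - e_ref
    alt_reads <- alt_reads - e_alt
  }
  list(counts = counts, depth = depth, ad_ref = ref_reads, ad_alt = alt_reads)
}

#' Simulate pooled sequencing of the two bulks
#'
#' Emulates whole-genome sequencing of the two DNA pools. At each marker
#' and bulk the total depth is Poisson with the bulk's configured mean;
#' each read draws its source haplotype uniformly (with replacement) from
#' the \code{2 x n_per_bulk} chromosomes in the pool, reports the true
#' base with probability \code{1 - error_rate} and a uniformly chosen
#' other base otherwise. A configurable fraction of markers is emitted as
#' indel-class records, and a configurable rate of markers spawns dense
#' artifact clusters (three SNPs within a 5-bp window, or an indel pair
#' less than 10 bp apart) so that the proximity filters have work to do.
#'
#' @param population a \code{bsa_population}.
#' @param bulks a \code{bsa_bulks} from \code{\link{select_bulks}}.
#' @param config the shared \code{\link{sim_config}}.
#' @return a \code{bulk_sites} data frame (see \code{\link{bulk_sites}}),
#'   sorted by chromosome and position, carrying per-base read counts for
#'   samples R01 (high bulk) and R02 (low bulk).
#' @export
simulate_bulk_reads <- function(population, bulks, config) {
  validate_sim_config(config)
  if (length(bulks$high) < 1L || length(bulks$low) < 1L)
    stop("both bulks must be non-empty", call. = FALSE)
  set.seed(config$seed + 2L)
  map <- population$map
  m <- nrow(map)

  freq_bulk <- function(idx) {
    (colSums(population$hap1[idx, , drop = FALSE]) +
       colSums(population$hap2[idx, , drop = FALSE])) / (2 * length(idx))
  }
  f_high <- freq_bulk(bulks$high)
  f_low <- freq_bulk(bulks$low)

  ref_b <- sample.int(4L, m, replace = TRUE)
  alt_b <- ((ref_b - 1L + sample.int(3L, m, replace = TRUE)) %% 4L) + 1L
  is_indel <- stats::runif(m) < config$indel_fraction
  if (any(map$is_causal)) is_indel[map$is_causal] <- FALSE

  bases <- c("A", "C", "G", "T")
  ref <- ifelse(is_indel, paste0(bases[ref_b], bases[alt_b]), bases[ref_b])
  alt <- ifelse(is_indel, bases[ref_b], bases[alt_b])

  r01 <- .pool_reads(f_high, config$depth_high, ref_b, alt_b, !is_indel,
                     config$error_rate)
  r02 <- .pool_reads(f_low, config$depth_low, ref_b, alt_b, !is_indel,
                     config$error_rate)

  sites <- data.frame(
    chrom = map$chrom, pos = map$pos, ref = ref, alt = alt,
    class = ifelse(is_indel, "indel", "SNP"),
    stringsAsFactors = FALSE)
  cnt <- cbind(r01$counts, r02$counts)
  colnames(cnt) <- c(paste0(bases, "_R01"), paste0(bases, "_R02"))
  sites <- cbind(sites, as.data.frame(cnt))
  sites$dp_R01 <- r01$depth;   sites$dp_R02 <- r02$depth
  sites$adr_R01 <- r01$ad_ref; sites$ada_R01 <- r01$ad_alt
  sites$adr_R02 <- r02$ad_ref; sites$ada_R02 <- r02$ad_alt

  sites <- rbind(sites, .artifact_sites(map, config))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  bulk_sites(sites, chrom_lengths = config$chrom_lengths)
}

# Dense artifact clusters planted near a random subset of markers: either
# two extra SNPs at +1/+2 bp (three SNPs in a 5-bp window) or an indel
# pair at +1/+6 bp (distance 5 < 10 bp). Artifact counts are unlinked
# noise at allele frequency 1/2 in both bulks.
.artifact_sites <- function(map, config) {
  hosts <- which(stats::runif(nrow(map)) < config$cluster_rate)
  # keep clusters clear of the next marker and the chromosome end
  ok <- vapply(hosts, function(i) {
    nxt <- if (i < nrow(map) && map$chrom[i + 1L] == map$chrom[i])
      map$pos[i + 1L] else Inf
    lim <- config$chrom_lengths[[map$chrom[i]]]
    map$pos[i] + 6 < min(nxt, lim) && !map$is_causal[i]
  }, logical(1))
  hosts <- hosts[ok]
  if (length(hosts) == 0L) return(NULL)

  bases <- c("A", "C", "G", "T")
  rows <- lapply(hosts, function(i) {
    as_pair <- stats::runif(1) < 0.5
    off <- if (as_pair) c(1L, 6L) else c(1L, 2L)
    do.call(rbind, lapply(off, function(o) {
      rb <- sample.int(4L, 1L)
      ab <- ((rb - 1L + sample.int(3L, 1L)) %% 4L) + 1L
      d1 <- stats::rpois(1L, config$depth_high)
      d2 <- stats::rpois(1L, config$depth_low)
      a1 <- stats::rbinom(1L, d1, 0.5); a2 <- stats::rbinom(1L, d2, 0.5)
      cnt <- matrix(0L, 2L, 4L)
      cnt[cbind(1:2, rb)] <- c(d1 - a1, d2 - a2)
      cnt[cbind(1:2, ab)] <- cnt[cbind(1:2, ab)] + c(a1, a2)
      data.frame(
        chrom = map$chrom[i], pos = map$pos[i] + o,
        ref = if (as_pair) paste0(bases[rb], bases[ab]) else bases[rb],
        alt = if (as_pair) bases[rb] else bases[ab],
        class = if (as_pair) "indel" else "SNP",
        A_R01 = cnt[1, 1], C_R01 = cnt[1, 2], G_R01 = cnt[1, 3], T_R01 = cnt[1, 4],
        A_R02 = cnt[2, 1], C_R02 = cnt[2, 2], G_R02 = cnt[2, 3], T_R02 = cnt[2, 4],
        dp_R01 = d1, dp_R02 = d2,
        adr_R01 = d1 - a1, ada_R01 = a1, adr_R02 = d2 - a2, ada_R02 = a2,
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: simulate the population, select the bulks,
#' sequence the pools, and optionally write the VCF. All randomness is
#' driven by \code{config$seed}; the same config yields byte-identical
#' output files.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_population plants to grow before phenotype selection.
#' @param vcf optional path; when given, the simulated sites are written
#'   as a two-sample VCF (see \code{\link{write_bulk_vcf}}).
#' @return list with \code{population}, \code{bulks}, \code{sites}, and
#'   (when written) \code{vcf}.
#' @export
simulate_bsa <- function(config, n_population = 125, vcf = NULL) {
  pop <- simulate_population(config, n_population)
  bulks <- select_bulks(pop, config)
  sites <- simulate_bulk_reads(pop, bulks, config)
  out <- list(population = pop, bulks = bulks, sites = sites)
  if (!is.null(vcf)) {
    write_bulk_vcf(sites, vcf)
    out$vcf <- vcf
  }
  out
}
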