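# Independent reference implementations and fixture builders used across
# the suite. These deliberately use the slowest, most literal algorithm
# available so they can arbitrate the vectorised package code.

BASES4 <- c("A", "C", "G", "T")

# Build a bulk_sites table from parallel vectors; count vectors are
# given as n x 4 matrices (defaults: depth 20 fixed on the ref base).
make_sites <- function(chrom, pos, class = "SNP", ref = "A", alt = "T",
                       c1 = NULL, c2 = NULL, chrom_lengths = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n); class <- rep_len(class, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (is.null(c1)) c1 <- matrix(rep(c(20L, 0L, 0L, 0L), each = n), n, 4)
  if (is.null(c2)) c2 <- matrix(rep(c(20L, 0L, 0L, 0L), each = n), n, 4)
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   class = class, stringsAsFactors = FALSE)
  cn <- cbind(c1, c2)
  colnames(cn) <- c(paste0(BASES4, "_R01"), paste0(BASES4, "_R02"))
  df <- cbind(df, as.data.frame(cn))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  bulk_sites(df, chrom_lengths = chrom_lengths)
}

# O(n^2) all-pairs reference of the three proximity rules, evaluated on
# the unfiltered set exactly as documented.
brute_proximity_survivors <- function(sites) {
  n <- nrow(sites)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || sites$chrom[i] != sites$chrom[j]) next
      d <- abs(sites$pos[i] - sites$pos[j])
      # rule a: both members of an indel pair closer than 10 bp
      if (sites$class[i] == "indel" && sites$class[j] == "indel" && d < 10)
        drop[i] <- TRUE
      # rule c: SNP within 5 bp of an indel
      if (sites$class[i] == "SNP" && sites$class[j] == "indel" && d <= 5)
        drop[i] <- TRUE
    }
  }
  # rule b: any 5-bp window holding > 2 SNPs removes all its SNPs
  for (i in seq_len(n)) {
    if (sites$class[i] != "SNP") next
    for (p in (sites$pos[i] - 4):sites$pos[i]) {
      in_win <- sites$chrom == sites$chrom[i] & sites$class == "SNP" &
        sites$pos >= p & sites$pos <= p + 4
      if (sum(in_win) > 2) drop[i] <- TRUE
    }
  }
  sites[!drop, , drop = FALSE]
}

# Literal per-window recomputation of the sliding-window mean.
brute_window_fit <- function(scores, window, step, min_snps, chrom_len) {
  centers <- seq(window / 2, chrom_len - window / 2, by = step)
  vapply(centers, function(cc) {
    sel <- scores$pos >= cc - window / 2 & scores$pos < cc + window / 2
    if (sum(sel) >= min_snps) mean(scores$ed_pow[sel]) else NA_real_
  }, numeric(1))
}

# One-sided enrichment P by explicit hypergeometric tail summation:
# P[X >= k] with X ~ Hypergeom(N, K, n), via binomial coefficients.
hyper_tail_p <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Random site set with planted pathological cases for the filter suite.
random_filter_sites <- function(n = 200, chroms = c("c1", "c2"), span = 5000) {
  pos <- sort(sample(span, n))
  chrom <- sort(sample(chroms, n, replace = TRUE))
  cls <- sample(c("SNP", "indel"), n, replace = TRUE, prob = c(0.85, 0.15))
  c1 <- t(vapply(seq_len(n), function(i) {
    v <- integer(4); v[sample(4, 2)] <- c(sample(0:30, 1), sample(0:30, 1)); v
  }, integer(4)))
  c2 <- t(vapply(seq_len(n), function(i) {
    v <- integer(4); v[sample(4, 2)] <- c(sample(0:30, 1), sample(0:30, 1)); v
  }, integer(4)))
  s <- make_sites(chrom, pos, class = cls,
                  ref = ifelse(cls == "indel", "AT", "A"),
                  alt = ifelse(cls == "indel", "A", "T"),
                  c1 = c1, c2 = c2)
  # deduplicate (chrom,pos) collisions from planting
  s[!duplicated(s[c("chrom", "pos")]), , drop = FALSE]
}

# Tiny hand-written AD-only VCF (two samples) as text lines.
adonly_vcf_lines <- function(rows,
                             samples = c("R01", "R02")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows)
}
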