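toy_regions <- function(chrom, start, end) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       peak = 1, n_snps = 1L, length = end - start + 1,
                       stringsAsFactors = FALSE),
            class = c("candidate_regions", "data.frame"))
}

toy_genes <- function(start, end, chrom = "c1") {
  data.frame(gene_id = sprintf("g%03d", seq_along(start)), chrom = chrom,
             start = start, end = end, strand = "+", stringsAsFactors = FALSE)
}

test_that("region membership is 1-bp overlap, not containment", {
  genes <- toy_genes(c(150, 301), c(250, 400))
  reg <- toy_regions("c1", 200, 300)
  got <- genes_in_regions(reg, genes)
  expect_identical(got[[1]], "g001")  # [150,250] overlaps [200,300]
  # [301,400] is adjacent under 1-based inclusive coords: no shared base
  expect_false("g002" %in% got[[1]])
})

test_that("region-gene overlap matches a brute-force interval check", {
  set.seed(53)
  n <- 1000
  gs <- sort(sample(1e6, n))
  genes <- toy_genes(gs, gs + sample(500:3000, n, TRUE))
  regions <- toy_regions("c1", c(1e5, 6e5), c(2e5, 7e5))
  got <- genes_in_regions(regions, genes)
  for (i in 1:2) {
    want <- genes$gene_id[genes$end >= regions$start[i] &
                            genes$start <= regions$end[i]]
    expect_setequal(got[[i]], want)
  }
  # empty regions and whole-genome regions behave as set bounds
  expect_length(genes_in_regions(regions[0, ], genes), 0L)
  all_in <- genes_in_regions(toy_regions("c1", 1, 2e6), genes)
  expect_setequal(all_in[[1]], genes$gene_id)
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  # region: 10 genes, 4 in pathway; genome: 100 genes, 10 in pathway
  all_genes <- sprintf("g%03d", 1:100)
  region <- all_genes[1:10]
  pw <- data.frame(gene_id = all_genes[c(1:4, 50:55)], pathway_id = "P")
  res <- pathway_enrichment(region, all_genes, pw)
  expect_identical(res$k, 4L)
  expect_identical(res$K, 10L)
  want <- hyper_tail_p(4, 10, 10, 100)
  expect_equal(res$p_value, want, tolerance = 1e-10)
  expect_true(res$significant)
})

test_that("a pathway covering every gene is degenerate and insignificant", {
  all_genes <- sprintf("g%03d", 1:50)
  pw <- data.frame(gene_id = all_genes, pathway_id = "everything")
  res <- pathway_enrichment(all_genes[1:5], all_genes, pw)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_true(is.nan(res$odds_ratio) || !is.finite(res$odds_ratio))
})

test_that("region genes outside the background are rejected", {
  pw <- data.frame(gene_id = "g1", pathway_id = "P")
  expect_error(pathway_enrichment("gX", c("g1", "g2"), pw), "background")
})

test_that("enrichment is invariant under consistent relabelling", {
  set.seed(59)
  all_genes <- sprintf("g%03d", 1:80)
  region <- sample(all_genes, 12)
  pw <- data.frame(gene_id = sample(all_genes, 30, replace = TRUE),
                   pathway_id = sample(c("a", "b", "c"), 30, replace = TRUE))
  relabel <- stats::setNames(sprintf("x%03d", sample(80)), all_genes)
  r1 <- pathway_enrichment(region, all_genes, pw)
  pw2 <- transform(pw, gene_id = unname(relabel[gene_id]))
  r2 <- pathway_enrichment(unname(relabel[region]), unname(relabel), pw2)
  expect_equal(r1[order(r1$pathway_id), "p_value"],
               r2[order(r2$pathway_id), "p_value"], tolerance = 1e-12)
})

test_that("the planted-enrichment fixture ranks its pathway first", {
  cfg <- sim_config(seed = 61)
  fix <- generate_annotation_fixture(
    cfg, n_genes = 100,
    planted = list(pathway = "pw_planted", chrom = "A06",
                   start = 1, end = 3e6, n_in_region = 4, n_total = 10))
  region_genes <- fix$genes$gene_id[fix$genes$chrom == "A06" &
                                      fix$genes$end >= 1 &
                                      fix$genes$start <= 3e6]
  expect_length(region_genes, 10L)
  res <- pathway_enrichment(region_genes, fix$genes$gene_id, fix$pathways)
  expect_identical(res$pathway_id[1], "pw_planted")
  expect_true(res$significant[1])
  # the planted table is exactly (k=4, K=10) against N=100
  expect_identical(res$k[res$pathway_id == "pw_planted"], 4L)
  expect_identical(res$K[res$pathway_id == "pw_planted"], 10L)
})

test_that("DEG cross-referencing keeps significant genes and tallies untested", {
  deg <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    contrast = c("apical", "basal", "apical", "apical"),
                    log2fc = c(2.1, 1.8, 0.2, -0.5),
                    adjusted_p = c(0.01, 0.2, 0.8, 0.04))
  got <- cross_reference_degs(c("g1", "g2", "g4"), deg)
  expect_identical(got$candidates$gene_id, "g1")
  expect_identical(got$candidates$contrasts, "apical")
  expect_identical(got$untested, "g4")
  expect_identical(got$n_tested, 2L)
  # g3 is significant but not a region gene
  expect_false("g3" %in% got$candidates$gene_id)
})

test_that("fixture DEGs inside the region are recovered exactly", {
  cfg <- sim_config(seed = 67)
  fix <- generate_annotation_fixture(
    cfg, n_genes = 90,
    planted = list(pathway = "pw_planted", chrom = "A06",
                   start = 1, end = 30e6, n_in_region = 4, n_total = 10),
    deg_in_region = 2, deg_background = 0, deg_coverage = 1)
  region_genes <- fix$genes$gene_id
  got <- cross_reference_degs(region_genes, fix$degs)
  expect_identical(nrow(got$candidates), 2L)
  expect_length(got$untested, 0L)
})

test_that("malformed DEG tables report the offending line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tadjusted_p",
               "g1\t1.5\t0.01",
               "g2\toops\t0.5"), path)
  expect_error(read_deg_table(path), "line 3")
  writeLines(c("gene_id\tlog2fc", "g1\t1.5"), path)
  expect_error(read_deg_table(path), "adjusted_p")
})

test_that("annotation fixtures round-trip through their standard formats", {
  cfg <- sim_config(chrom_lengths = c(c1 = 10e6, c2 = 5e6), causal_pos = 5e6,
                    causal_chrom = "c1", seed = 71)
  dir <- tempfile()
  fix <- generate_annotation_fixture(cfg, out_dir = dir, n_genes = 60)
  genes <- read_gene_gff(fix$paths$gff)
  expect_equal(nrow(genes), 60)
  expect_equal(genes$gene_id, fix$genes$gene_id)
  expect_equal(genes$start, fix$genes$start)
  expect_equal(genes$end, fix$genes$end)
  # gene intervals never overlap within a chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  pw <- read_pathway_table(fix$paths$pathways)
  expect_identical(sort(names(pw)), c("gene_id", "pathway_id"))
  deg <- read_deg_table(fix$paths$degs)
  expect_true(all(c("gene_id", "log2fc", "adjusted_p") %in% names(deg)))

  # determinism: same seed, identical files
  dir2 <- tempfile()
  generate_annotation_fixture(cfg, out_dir = dir2, n_genes = 60)
  for (f in c("genes.gff3", "pathways.tsv", "degs.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }

  # zero genes: schema-valid empty fixtures
  fix0 <- generate_annotation_fixture(cfg, out_dir = tempfile(), n_genes = 0)
  expect_identical(nrow(fix0$genes), 0L)
  expect_identical(nrow(read_pathway_table(fix0$paths$pathways)), 0L)

  # planted interval outside the genome is a configuration error
  expect_error(generate_annotation_fixture(
    cfg, planted = list(pathway = "p", chrom = "c1", start = 1, end = 99e6,
                        n_in_region = 1, n_total = 2)), "outside")
})
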