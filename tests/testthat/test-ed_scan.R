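cnt <- function(...) matrix(as.integer(c(...)), 1, 4, byrow = TRUE)

test_that("base frequencies normalise counts per bulk", {
  s <- make_sites("c1", 100, c1 = cnt(10, 0, 0, 10), c2 = cnt(30, 0, 10, 0))
  f <- base_frequencies(s)
  expect_equal(f$r01[1, ], c(A = 0.5, C = 0, G = 0, T = 0.5))
  expect_equal(f$r02[1, ], c(A = 0.75, C = 0, G = 0.25, T = 0))
  set.seed(3)
  n <- 200
  c1 <- matrix(sample(0:30, n * 4, TRUE), n, 4); c1[, 1] <- c1[, 1] + 1L
  c2 <- matrix(sample(0:30, n * 4, TRUE), n, 4); c2[, 1] <- c2[, 1] + 1L
  f <- base_frequencies(make_sites("c1", seq_len(n) * 10, c1 = c1, c2 = c2))
  expect_equal(rowSums(f$r01), rep(1, n), tolerance = 1e-12)
  expect_equal(rowSums(f$r02), rep(1, n), tolerance = 1e-12)
  s0 <- make_sites("c1", 100, c1 = cnt(0, 0, 0, 0), c2 = cnt(1, 0, 0, 0))
  expect_error(base_frequencies(s0), "filter_ed_input")
})

test_that("the ED statistic matches its closed forms", {
  same <- make_sites("c1", 100, c1 = cnt(5, 5, 0, 0), c2 = cnt(10, 10, 0, 0))
  expect_equal(ed_statistic(same)$ed, 0)
  expect_equal(ed_statistic(same)$ed_pow, 0)

  opp <- make_sites("c1", 100, c1 = cnt(12, 0, 0, 0), c2 = cnt(0, 0, 0, 7))
  sc <- ed_statistic(opp)
  expect_equal(sc$ed, sqrt(2), tolerance = 1e-12)
  expect_equal(sc$ed_pow, 2^2.5, tolerance = 1e-12)

  mid <- make_sites("c1", 100, c1 = cnt(30, 0, 10, 0), c2 = cnt(10, 0, 30, 0))
  sc <- ed_statistic(mid)
  expect_equal(sc$ed, sqrt(0.5), tolerance = 1e-12)
  expect_equal(sc$ed_pow, 0.5^2.5, tolerance = 1e-12)

  expect_error(ed_statistic(opp, power = 0.5), "power")
})

test_that("biallelic sites obey ED = sqrt(2)|df| and ED is bounded", {
  set.seed(19)
  n <- 2000
  a1 <- sample(0:40, n, TRUE); d1 <- sample(1:40, n, TRUE) + a1
  a2 <- sample(0:40, n, TRUE); d2 <- sample(1:40, n, TRUE) + a2
  s <- make_sites("c1", seq_len(n) * 10,
                  c1 = cbind(a1, d1 - a1, 0L, 0L),
                  c2 = cbind(a2, d2 - a2, 0L, 0L))
  sc <- ed_statistic(s)
  expect_equal(sc$ed, sqrt(2) * abs(a1 / d1 - a2 / d2), tolerance = 1e-12)
  expect_true(all(sc$ed >= 0 & sc$ed <= sqrt(2) + 1e-12))
})

test_that("ED grows with the biallelic frequency difference", {
  df <- seq(0, 1, by = 0.05)
  eds <- vapply(df, function(d) {
    a1 <- round(100 * (0.5 + d / 2)); a2 <- round(100 * (0.5 - d / 2))
    s <- make_sites("c1", 100, c1 = cnt(a1, 100 - a1, 0, 0),
                    c2 = cnt(a2, 100 - a2, 0, 0))
    ed_statistic(s)$ed
  }, numeric(1))
  expect_true(all(diff(eds) >= -1e-12))
  expect_true(all(diff(eds^5) >= -1e-12))
})

test_that("with power 1 the powered ED equals ED", {
  set.seed(23)
  n <- 50
  s <- make_sites("c1", seq_len(n) * 10,
                  c1 = cbind(sample(1:30, n, TRUE), sample(0:30, n, TRUE), 0L, 0L),
                  c2 = cbind(sample(1:30, n, TRUE), sample(0:30, n, TRUE), 0L, 0L))
  sc <- ed_statistic(s, power = 1)
  expect_identical(sc$ed, sc$ed_pow)
})

test_that("sliding-window fits reproduce simple signals", {
  # constant signal: every defined window fits exactly that constant
  n <- 100
  s <- make_sites("c1", seq_len(n) * 1000,
                  c1 = cnt(20, 0, 0, 0)[rep(1, n), ],
                  c2 = cnt(0, 0, 0, 20)[rep(1, n), ],
                  chrom_lengths = c(c1 = 1e5))
  sc <- ed_statistic(s)
  sc$ed_pow <- rep(0.2, n)
  tr <- sliding_window_fit(sc, window = 2e4, step = 5e3, min_snps = 1)
  expect_true(all(abs(tr$value - 0.2) < 1e-12))

  # single SNP per window: the fit equals that SNP's powered ED
  s1 <- make_sites("c1", c(5000, 15000, 25000),
                   c1 = matrix(c(20, 0, 0, 0), 3, 4, byrow = TRUE),
                   c2 = matrix(c(10, 10, 0, 0), 3, 4, byrow = TRUE),
                   chrom_lengths = c(c1 = 3e4))
  sc1 <- ed_statistic(s1)
  tr1 <- sliding_window_fit(sc1, window = 1e4, step = 1e4, min_snps = 1)
  expect_equal(tr1$value, sc1$ed_pow, tolerance = 1e-12)
  expect_equal(tr1$n_snps, rep(1L, 3))
})

test_that("the window fit equals a brute-force recomputation", {
  set.seed(29)
  n <- 1000
  pos <- sort(sample(1e6, n))
  s <- make_sites("c1", pos,
                  c1 = cbind(sample(1:30, n, TRUE), sample(0:30, n, TRUE), 0L, 0L),
                  c2 = cbind(sample(1:30, n, TRUE), sample(0:30, n, TRUE), 0L, 0L),
                  chrom_lengths = c(c1 = 1e6))
  sc <- ed_statistic(s)
  tr <- sliding_window_fit(sc, window = 1e5, step = 1e4, min_snps = 10)
  want <- brute_window_fit(sc, window = 1e5, step = 1e4, min_snps = 10,
                           chrom_len = 1e6)
  expect_equal(tr$value, want, tolerance = 1e-12)
})

test_that("the threshold is median + 3 sample SD of defined windows", {
  tr <- data.frame(chrom = "c", center = 1:5, value = c(1, 2, 3, 4, 5),
                   n_snps = 10L)
  th <- ed_threshold(tr)
  expect_equal(th$median, 3)
  expect_equal(th$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(th$tau, 3 + 3 * sqrt(2.5), tolerance = 1e-12)
  expect_equal(round(th$tau, 6), 7.743416)

  # permutation invariance and NA windows excluded
  tr2 <- tr[sample(5), ]; tr2 <- rbind(tr2, data.frame(
    chrom = "c", center = 6, value = NA_real_, n_snps = 0L))
  expect_equal(ed_threshold(tr2)$tau, th$tau)

  expect_error(ed_threshold(tr[1, ]), "2 defined windows")
})

test_that("constant tracks yield zero regions under the strict threshold", {
  tr <- data.frame(chrom = "c", center = seq(5e5, 5e6, by = 1e5),
                   value = 0.4, n_snps = 20L)
  attr(tr, "window") <- 1e6
  class(tr) <- c("fitted_track", class(tr))
  th <- ed_threshold(tr)
  expect_equal(th$sd, 0)
  expect_equal(th$tau, 0.4)
  expect_identical(nrow(call_candidate_regions(tr, th)), 0L)
})

test_that("threshold runs merge into one region per peak", {
  w <- 1e4
  vals <- c(rep(0.1, 8), 0.9, 0.95, 0.9, rep(0.1, 8))
  tr <- data.frame(chrom = "c1", center = seq(w / 2, by = w,
                                              length.out = length(vals)),
                   value = vals, n_snps = 5L)
  attr(tr, "window") <- w
  class(tr) <- c("fitted_track", class(tr))
  reg <- call_candidate_regions(tr, 0.5)
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$start, tr$center[9] - w / 2)
  expect_equal(reg$end, tr$center[11] + w / 2 - 1)
  expect_equal(reg$peak, 0.95)
  expect_equal(reg$length, reg$end - reg$start + 1)

  # an undefined window splits the run unless bridged
  tr$value[10] <- NA
  expect_identical(nrow(call_candidate_regions(tr, 0.5)), 2L)
  expect_identical(nrow(call_candidate_regions(tr, 0.5, gap_tolerance = 1)), 1L)

  # nothing above tau -> no regions
  expect_identical(nrow(call_candidate_regions(tr, 2)), 0L)
})

test_that("swapping bulk labels leaves the whole scan invariant", {
  cfg <- sim_config(chrom_lengths = c(c1 = 6e6), marker_spacing = 6e3,
                    causal_pos = 3e6, seed = 37)
  sim <- simulate_bsa(cfg, n_population = 150)
  swap <- sim$sites
  for (b in BASES4) {
    tmp <- swap[[paste0(b, "_R01")]]
    swap[[paste0(b, "_R01")]] <- swap[[paste0(b, "_R02")]]
    swap[[paste0(b, "_R02")]] <- tmp
  }
  for (suf in c("dp", "adr", "ada")) {
    tmp <- swap[[paste0(suf, "_R01")]]
    swap[[paste0(suf, "_R01")]] <- swap[[paste0(suf, "_R02")]]
    swap[[paste0(suf, "_R02")]] <- tmp
  }
  a <- ed_scan(sim$sites, window = 1e6)
  b <- ed_scan(swap, window = 1e6)
  expect_equal(a$scores$ed, b$scores$ed, tolerance = 1e-12)
  expect_equal(a$track$value, b$track$value, tolerance = 1e-12)
  expect_equal(a$threshold$tau, b$threshold$tau, tolerance = 1e-12)
  expect_equal(a$regions, b$regions, tolerance = 1e-12)
})

test_that("masked intervals drop their SNPs from the scan", {
  cfg <- sim_config(chrom_lengths = c(c1 = 6e6), marker_spacing = 6e3,
                    causal_pos = 3e6, seed = 41)
  sim <- simulate_bsa(cfg, n_population = 150)
  unmasked <- ed_scan(sim$sites, window = 1e6)
  masked <- ed_scan(sim$sites, window = 1e6,
                    mask = data.frame(chrom = "c1", start = 1, end = 1e6))
  expect_true(all(masked$scores$pos > 1e6))
  expect_lt(nrow(masked$scores), nrow(unmasked$scores))
})

test_that("the scan object prints, summarises and plots", {
  cfg <- sim_config(chrom_lengths = c(c1 = 6e6), marker_spacing = 6e3,
                    causal_pos = 3e6, seed = 43)
  sim <- simulate_bsa(cfg, n_population = 150)
  scan <- ed_scan(sim$sites, window = 1e6)
  expect_output(print(scan), "Euclidean-distance genome scan")
  s <- summary(scan)
  expect_s3_class(s, "summary.ed_scan")
  expect_output(print(s), "windows defined")
  png <- tempfile(fileext = ".png")
  grDevices::png(png)
  expect_silent(plot(scan))
  grDevices::dev.off()
  expect_true(file.exists(png))
})
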