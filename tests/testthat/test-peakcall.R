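# Poisson LRT peak caller: background, per-base test, CIs, peaks,
# force-calling, pseudo-replicates, motif-stage filters

test_that("estimate_background is a window mean absorbing ploidy steps", {
  tr <- flat_track(10, L = 30000)
  bg <- estimate_background(tr, W_bg = 1000)
  expect_equal(unique(bg$b$chr1), 10)

  # step track: transition confined to within W_bg of the boundary
  gi <- genome_index(c(chr1 = 40000))
  v <- c(rep(10, 20000), rep(30, 20000))
  tr2 <- coverage_track(list(chr1 = v), gi, n_fragments = 100)
  bg2 <- estimate_background(tr2, W_bg = 2000)
  expect_equal(bg2$b$chr1[10000], 10)
  expect_equal(bg2$b$chr1[30000], 30)
  mid <- bg2$b$chr1[19000:21000]
  expect_true(all(diff(mid) >= 0))

  # Poisson noise: window mean within 5 SE of the true rate
  set.seed(13)
  v3 <- as.numeric(rpois(60000, 10))
  tr3 <- coverage_track(list(chr1 = v3), genome_index(c(chr1 = 60000)),
                        n_fragments = 1000)
  bg3 <- estimate_background(tr3, W_bg = 10000)
  se <- sqrt(10 / 10000)
  inner <- bg3$b$chr1[5001:55000]
  expect_lt(max(abs(inner - 10)), 5 * se)

  expect_warning(estimate_background(flat_track(0, 2000), W_bg = 1000),
                 "all-zero")
  expect_error(estimate_background(flat_track(1, 2000), W_bg = 500),
               "at least 1000")
})

test_that("base_test reproduces the closed-form MLE and LRT", {
  # boundary: counts equal to expectation give e = 0, p = 1
  r0 <- base_test(10, 10, b = 10, r = c(1, 1))
  expect_equal(r0$e, 0)
  expect_equal(r0$p, 1)

  # frozen oracle: numeric maximization of the two-replicate Poisson
  # likelihood gives e = 2 and Lambda = 120*log(3) - 80 for x1 = x2 = 30,
  # b = 10, r = (1, 1)
  r1 <- base_test(30, 30, b = 10, r = c(1, 1), ci = TRUE)
  expect_equal(r1$e, 2.0)
  expect_equal(r1$lambda, 120 * log(3) - 80, tolerance = 1e-12)
  expect_equal(r1$p, 0.5 * pchisq(120 * log(3) - 80, 1,
                                  lower.tail = FALSE))
  # the closed form matches a grid maximization of the likelihood
  ll <- function(e) dpois(30, 10 * (1 + e), log = TRUE) * 2
  grid <- seq(0, 10, by = 1e-4)
  expect_equal(grid[which.max(ll(grid))], 2.0, tolerance = 1e-3)
  # profile CI brackets the MLE and excludes 0 for this strong signal
  expect_lt(r1$e_lo, 2)
  expect_gt(r1$e_hi, 2)
  expect_gt(r1$e_lo, 0)

  expect_error(base_test(5, 5, b = 0, r = c(1, 1)), "positive")
})

test_that("p is non-increasing in the total count (monotonicity)", {
  p <- base_test(10:60, rep(20, 51), b = 15, r = c(1, 1))$p
  expect_true(all(diff(p) <= 1e-15))
})

test_that("null counts give calibrated type-I error", {
  set.seed(17)
  n <- 30000
  b <- 50
  x1 <- rpois(n, b); x2 <- rpois(n, b)
  p <- base_test(x1, x2, b = b, r = c(1, 1))$p
  for (alpha in c(0.05, 0.01)) {
    emp <- mean(p < alpha)
    tol <- 3 * sqrt(alpha * (1 - alpha) / n)
    expect_lt(abs(emp - alpha), tol + 1e-12)
  }
})

test_that("profile CI covers the true enrichment at nominal rate and the
          estimator is consistent", {
  set.seed(19)
  e_true <- 1.5
  b <- 100                      # expected counts 2*b*(1+e) = 500
  n <- 1000
  x1 <- rpois(n, b * (1 + e_true)); x2 <- rpois(n, b * (1 + e_true))
  res <- base_test(x1, x2, b = b, r = c(1, 1), ci = TRUE)
  cover <- mean(res$e_lo <= e_true & res$e_hi >= e_true)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
  expect_lt(abs(median(res$e) - e_true), 0.05)
})

test_that("call_peaks recovers planted sites and keeps distant sites
          separate", {
  cfg <- sim_config(genome_length = 1e6, block_length = 1e6,
                    gc_blocks = 0.45, ploidy_blocks = 1, n_sites = 40,
                    occupancy_b = -100, seed = 41L)
  sim <- simulate_genome(cfg)
  fr <- simulate_chip(sim$truth, cfg)
  cov1 <- fragments_to_coverage(fr$rep1, sim$genome, "r1")
  cov2 <- fragments_to_coverage(fr$rep2, sim$genome, "r2")
  covi <- fragments_to_coverage(fr$input, sim$genome, "in")
  pk <- call_peaks(cov1, cov2, covi)
  # every planted site recovered within 100 bp, one peak per site
  d <- vapply(sim$truth$sites$center, function(ctr)
    min(abs(pk$center - ctr)), 0)
  expect_true(all(d <= 100))
  # sites are ~25 kb apart: no merging, peak count == site count
  expect_equal(nrow(pk), 40)
  expect_true(all(pk$start <= pk$center & pk$center < pk$end))
  expect_true(all(pk$e_lo <= pk$e & pk$e <= pk$e_hi))

  # null tracks yield no peaks at alpha = 1e-6
  cfg0 <- sim_config(genome_length = 2e5, block_length = 2e5,
                     gc_blocks = 0.45, ploidy_blocks = 1, n_sites = 0,
                     seed = 43L)
  sim0 <- simulate_genome(cfg0)
  fr0 <- simulate_chip(sim0$truth, cfg0)
  pk0 <- call_peaks(fragments_to_coverage(fr0$rep1, sim0$genome),
                    fragments_to_coverage(fr0$rep2, sim0$genome),
                    fragments_to_coverage(fr0$input, sim0$genome))
  expect_equal(nrow(pk0), 0)
})

test_that("pseudo_replicates split fairly, deterministically, and
          conserve fragments", {
  set.seed(23)
  gi <- genome_index(c(chr1 = 1e5))
  start <- floor(runif(10000, 0, 9e4))
  fr <- fragment_set(rep("chr1", 10000), start, start + 100)
  sp <- pseudo_replicates(fr, seed = 7L)
  expect_equal(nrow(sp[[1]]) + nrow(sp[[2]]), 10000)
  expect_lt(abs(nrow(sp[[1]]) - 5000), 4 * sqrt(2500))
  sp2 <- pseudo_replicates(fr, seed = 7L)
  expect_identical(sp[[1]], sp2[[1]])
  # union equals the input set
  both <- rbind(as.data.frame(sp[[1]]), as.data.frame(sp[[2]]))
  expect_equal(sort(both$start), sort(fr$start))
  expect_error(pseudo_replicates(fr[1, , drop = FALSE]), "at least 2")
})

test_that("force_call flags low-input windows and detects planted
          enrichment", {
  cfg <- sim_config(genome_length = 5e5, block_length = 5e5,
                    gc_blocks = 0.45, ploidy_blocks = 1, n_sites = 20,
                    occupancy_b = -100, seed = 47L)
  sim <- simulate_genome(cfg)
  fr <- simulate_chip(sim$truth, cfg)
  cov1 <- fragments_to_coverage(fr$rep1, sim$genome, "r1")
  covi <- fragments_to_coverage(fr$input, sim$genome, "in")
  bg <- estimate_background(covi)
  iv <- interval_set(sim$truth$sites$chrom,
                     pmax(sim$truth$sites$center - 500, 0),
                     sim$truth$sites$center + 500)
  fc <- force_call(iv, cov1, covi, bg)
  expect_true(all(fc$p < 1e-3))     # lambda = 4, ample depth
  expect_true(all(fc$defined))

  # null windows: p-values not anticonservative (one-sided test)
  null_iv <- interval_set(rep("chr1", 200),
                          seq(5000, 404000, length.out = 200),
                          seq(5000, 404000, length.out = 200) + 1000)
  # displace away from sites
  keep <- vapply(seq_len(nrow(null_iv)), function(i)
    all(abs(sim$truth$sites$center - null_iv$start[i]) > 2000), TRUE)
  fcn <- force_call(null_iv[keep, ], cov1, covi, bg)
  expect_lt(mean(fcn$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(fcn)))

  # undefined when input reads <= 5: empty input region
  gi <- genome_index(c(chr1 = 5000))
  zl <- coverage_track(list(chr1 = c(rep(5, 2500), rep(0, 2500))), gi,
                       n_fragments = 100)
  sm <- coverage_track(list(chr1 = rep(5, 5000)), gi, n_fragments = 100)
  suppressWarnings({
    bg0 <- estimate_background(zl, W_bg = 1000)
    fc0 <- force_call(interval_set("chr1", 3500, 4500), sm, zl, bg0)
  })
  expect_false(fc0$defined)
  expect_error(force_call(interval_set("chr1", 4500, 5500), sm, zl, bg0),
               "outside")
})

test_that("filter_peaks_for_motifs applies the six stringent criteria", {
  mk <- function(n, p = 1e-12, e = 3, ciw = 10, x = 30, y = 10,
                 start = NULL) {
    if (is.null(start)) start <- seq(0, by = 1000, length.out = n)
    df <- data.frame(chrom = "chr1", start = start, end = start + 100,
                     center = start + 50, p = p, e = e,
                     e_lo = e - ciw / 2, e_hi = e + ciw / 2,
                     x1 = ceiling(x / 2), x2 = floor(x / 2), y = y)
    class(df) <- c("PeakSet", "data.frame")
    df
  }
  base <- mk(100, y = rep(10, 100))
  expect_equal(nrow(filter_peaks_for_motifs(base)), 100)

  # enrichment <= 2 excluded
  weak <- base; weak$e[1] <- 1.5
  expect_equal(nrow(filter_peaks_for_motifs(weak)), 99)
  # combined replicate reads below 30 excluded
  low <- base; low$x1[2] <- 14; low$x2[2] <- 15
  expect_equal(nrow(filter_peaks_for_motifs(low)), 99)
  # p-value above the stringent threshold excluded
  soft <- base; soft$p[3] <- 1e-8
  expect_equal(nrow(filter_peaks_for_motifs(soft)), 99)
  # wide CI excluded
  wide <- base; wide$e_hi[4] <- wide$e_lo[4] + 60
  expect_equal(nrow(filter_peaks_for_motifs(wide)), 99)
  # repeat overlap excluded
  reps <- interval_set("chr1", 0, 150)
  expect_equal(nrow(filter_peaks_for_motifs(base, repeats = reps)), 99)
  # input-coverage percentile filter: outliers on y dropped
  yq <- base; yq$y <- c(rep(10, 80), seq(100, 290, by = 10))
  expect_lt(nrow(filter_peaks_for_motifs(yq)), 100)
  # ranking contract: sorted by decreasing enrichment, top_n cap
  mix <- mk(50, e = runif(50, 2.5, 8))
  out <- filter_peaks_for_motifs(mix, top_n = 20)
  expect_equal(nrow(out), 20)
  expect_true(all(diff(out$e) <= 0))
})
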