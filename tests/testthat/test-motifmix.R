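# mixture motif discovery: seeding, EM refinement, exact-inference oracle,
# scanning, filters

test_that("extract_peak_sequences windows, excludes N and edge peaks", {
  g <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))   # 2000 bp
  pk <- data.frame(chrom = "chr1", center = c(1000, 60, 1500))
  s <- suppressMessages(extract_peak_sequences(pk, g, width = 300))
  expect_equal(length(s), 2)            # the center-60 peak is skipped
  expect_equal(unname(nchar(s)), c(300, 300))
  expect_equal(attr(s, "peak_index"), c(1L, 3L))
  # exact window arithmetic: [center - 150, center + 150)
  expect_equal(unname(s[1]), unname(substr(g, 1000 - 150 + 1, 1000 + 150)))
  # N-containing sequences excluded
  g2 <- c(chr1 = paste0(strrep("A", 900), "N", strrep("C", 1099)))
  pk2 <- data.frame(chrom = "chr1", center = c(901, 1500))
  s2 <- suppressMessages(extract_peak_sequences(pk2, g2, width = 300))
  expect_equal(length(s2), 1)
})

test_that("seed_motif picks the centrally enriched 10-mer and builds the
          0.7/0.1 PWM", {
  set.seed(61)
  seqs <- random_seqs(300, 300)
  word <- "ACGTACGTAC"
  for (i in 1:150) {
    pos <- 146 + sample(-30:30, 1)     # central placement
    substr(seqs[i], pos, pos + 9) <- word
  }
  pwm <- seed_motif(seqs)
  km <- attr(pwm, "kmer")
  expect_true(km == word || km == revcomp_str(word))
  expect_gt(attr(pwm, "central_ratio"), 2)
  expect_equal(dim(pwm), c(10, 4))
  idx <- match(strsplit(km, "")[[1]], BASES4)
  expect_true(all(pwm[cbind(1:10, idx)] == 0.7))
  expect_true(all(pwm[pwm != 0.7] == 0.1))

  # null sequences: the selected word is rare, so its central ratio is a
  # noisy maximum over the top 50 words -- bounded, but not the clean
  # planted signal (the planted case pins the word identity itself)
  set.seed(62)
  null_ratio <- attr(seed_motif(random_seqs(1000, 300)), "central_ratio")
  expect_lt(null_ratio, 2.905)   # a fully central word would exceed this
  expect_gt(null_ratio, 0.2)
  expect_error(seed_motif(random_seqs(50, 300)), "at least 100")
})

test_that("mixture posteriors match exhaustive enumeration on toy
          sequences", {
  set.seed(67)
  bg <- fit_background(random_seqs(50, 30, gc = 0.4))
  pwm1 <- consensus_pwm("ACGT", major = 0.7)
  pwm2 <- consensus_pwm("GGAT", major = 0.8)
  model <- motif_mixture(list(pwm1, pwm2), c(0.3, 0.2), bg)
  seqs <- c("ACGTACGT", "TTTTTTTT", "ATCCGGAT", "ACGT", "GG")
  enc <- meiomap:::encode_seqs(seqs)
  bgl <- meiomap:::bg_loglik_vectors(enc, bg)
  est <- meiomap:::motif_estep_cpp(enc, bgl, lapply(model$pwms, log),
                                   log(c(0.5, 0.3, 0.2)), TRUE)
  oracle <- oracle_posterior(seqs, model$pwms, c(0.3, 0.2), bg)
  expect_equal(est$post, oracle, tolerance = 1e-9)
  expect_equal(rowSums(est$post), rep(1, 5), tolerance = 1e-12)
})

test_that("EM refinement sharpens a noiseless planted motif and its
          log-likelihood is non-decreasing", {
  set.seed(71)
  word <- "TCATGCATGA"
  seqs <- random_seqs(200, 60)
  for (i in seq_along(seqs)) substr(seqs[i], 26, 35) <- word
  bg <- fit_background(seqs)
  seed_pwm <- consensus_pwm(word, major = 0.7)
  model <- refine_motif(motif_mixture(list(seed_pwm), 0.3, bg), seqs,
                        iters = 50, extend_ic = 2)   # no extension
  idx <- match(strsplit(word, "")[[1]], BASES4)
  expect_true(all(model$pwms[[1]][cbind(1:10, idx)] >= 0.9))
  expect_gt(model$pi, 0.9)
  expect_true(all(diff(model$loglik) >= -1e-6))
})

test_that("pure background yields no motif that survives the filters", {
  set.seed(73)
  seqs <- random_seqs(250, 300)
  model <- suppressMessages(
    discover_motifs(seqs, max_seeds = 2, seed_iters = 40,
                    joint_iters = 40))
  if (length(model$pwms) > 0) {
    kept <- filter_motifs(model, seqs)
    expect_equal(length(kept$pwms), 0)
  } else {
    expect_equal(length(model$pwms), 0)
  }
})

test_that("force_scan reports exact embeddings with strand symmetry and
          rarely matches background", {
  set.seed(79)
  word <- "CCTCCCTAGCCATC"
  bgseqs <- random_seqs(300, 100)
  bg <- fit_background(bgseqs)
  model <- motif_mixture(list(consensus_pwm(word)), 0.5, bg)

  s1 <- bgseqs[1]
  substr(s1, 41, 54) <- word
  m1 <- force_scan(model, s1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$start, 40)            # 0-based
  expect_equal(m1$strand, "+")
  expect_gt(m1$posterior, 0.99)

  # reverse-complemented embedding: same motif, minus strand, mirrored
  s2 <- paste(rev(strsplit(chartr("ACGT", "TGCA", s1), "")[[1]]),
              collapse = "")
  m2 <- force_scan(model, s2)
  expect_equal(m2$strand, "-")
  expect_equal(m2$start, nchar(s2) - 14 - 40)
  expect_gt(m2$posterior, 0.99)

  # background sequences: match rate below 1%
  mb <- force_scan(model, bgseqs)
  expect_lt(nrow(mb) / length(bgseqs), 0.01)

  # sequence shorter than the PWM yields no match
  expect_equal(nrow(force_scan(model, "ACGTAC")), 0)
})

test_that("filter_motifs enforces centrality and information content", {
  set.seed(83)
  word <- "TGCATCATGGCA"
  central <- random_seqs(200, 300)
  for (i in 1:180) {
    pos <- 145 + sample(-20:20, 1)
    substr(central[i], pos, pos + 11) <- word
  }
  scattered <- random_seqs(200, 300)
  for (i in 1:180) {
    pos <- sample(c(10:60, 230:280), 1)   # far from the center
    substr(scattered[i], pos, pos + 11) <- word
  }
  bg <- fit_background(central)
  pwm <- consensus_pwm(word)
  uniform <- matrix(0.25, 10, 4, dimnames = list(NULL, BASES4))

  mod_c <- motif_mixture(list(pwm, uniform), c(0.45, 0.45), bg)
  kept <- filter_motifs(mod_c, central)
  expect_equal(attr(kept, "kept"), 1L)    # degenerate motif removed

  mod_s <- motif_mixture(list(pwm), 0.9, bg)
  kept_s <- filter_motifs(mod_s, scattered)
  expect_equal(length(kept_s$pwms), 0)    # off-center matches removed
})

test_that("refinement is strand-symmetric and reproducible", {
  set.seed(89)
  word <- "GGATCCTTAA"
  seqs <- random_seqs(150, 80)
  for (i in 1:120) {
    pos <- sample(20:50, 1)
    substr(seqs[i], pos, pos + 9) <- word
  }
  bg <- fit_background(seqs)
  m_fwd <- refine_motif(motif_mixture(list(consensus_pwm(word, 0.7)),
                                      0.3, bg), seqs, iters = 20,
                        extend_ic = 2)
  rcseqs <- vapply(seqs, revcomp_str, "", USE.NAMES = FALSE)
  bg_rc <- fit_background(rcseqs)
  m_rev <- refine_motif(
    motif_mixture(list(consensus_pwm(revcomp_str(word), 0.7)), 0.3,
                  bg_rc), rcseqs, iters = 20, extend_ic = 2)
  rcp <- m_rev$pwms[[1]][rev(seq_len(nrow(m_rev$pwms[[1]]))),
                         c(4, 3, 2, 1)]
  # the fitted background model is not exactly strand-symmetric, so the
  # refined columns agree to ~1e-5 rather than machine precision
  expect_equal(unname(m_fwd$pwms[[1]]), unname(rcp), tolerance = 5e-3)

  # bit-identical reruns under the same seed
  d1 <- discover_motifs(seqs, max_seeds = 2, seed_iters = 30,
                        joint_iters = 30, seed = 5L)
  d2 <- discover_motifs(seqs, max_seeds = 2, seed_iters = 30,
                        joint_iters = 30, seed = 5L)
  expect_identical(d1$pwms, d2$pwms)
  expect_identical(d1$pi, d2$pi)
})

test_that("MEME format round-trips motifs", {
  set.seed(97)
  bg <- fit_background(random_seqs(120, 50))
  m <- motif_mixture(list(consensus_pwm("ACGTTGCA"),
                          consensus_pwm("TTGACGTCAA")), c(0.4, 0.3), bg)
  tf <- tempfile(fileext = ".meme")
  write_meme(m, tf)
  back <- read_meme(tf)
  expect_equal(length(back$pwms), 2)
  for (k in 1:2)
    expect_equal(unname(back$pwms[[k]]), unname(m$pwms[[k]]),
                 tolerance = 1e-5)
  expect_equal(pwm_consensus(back$pwms[[2]]), "TTGACGTCAA")
})
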