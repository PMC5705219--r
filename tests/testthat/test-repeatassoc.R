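# consensus alignment, k-mer presence, logistic association machinery

test_that("align_to_consensus maps coordinates through substitutions and
          indels", {
  cons <- paste(rep(c("ACGTTGCA", "GGATCCTA"), 8), collapse = "")  # 128 bp
  # identity
  al <- align_to_consensus(cons, cons)
  expect_equal(al$map[[1]], 0:(nchar(cons) - 1))
  # single substitution keeps coordinates
  sub <- cons
  substr(sub, 60, 60) <- if (substr(cons, 60, 60) == "T") "G" else "T"
  al2 <- align_to_consensus(sub, cons)
  expect_equal(al2$map[[1]], 0:(nchar(cons) - 1))
  expect_lt(al2$score, al$score)
  # 1-bp deletion at a position whose neighbors differ (no gap-placement
  # tie): that consensus coordinate is skipped in the map
  set.seed(71)
  cons_r <- paste(sample(BASES4, 128, replace = TRUE), collapse = "")
  ch <- strsplit(cons_r, "")[[1]]
  d1 <- which(ch[60:100] != ch[61:101] & ch[59:99] != ch[60:100])[1] + 59
  del <- paste0(substr(cons_r, 1, d1 - 1),
                substr(cons_r, d1 + 1, nchar(cons_r)))
  al3 <- align_to_consensus(del, cons_r)
  mapped <- al3$map[[1]]
  expect_equal(length(mapped), nchar(cons_r) - 1)
  expect_false((d1 - 1) %in% mapped)
  expect_equal(setdiff(0:(nchar(cons_r) - 1), mapped), d1 - 1)
  # short copies flagged
  al4 <- align_to_consensus(substr(cons, 1, 40), cons)
  expect_true(al4$flagged)
  expect_error(align_to_consensus("ACGT", "ACGTACGT"), "consensus")
})

test_that("alignment agrees with a dynamic-programming oracle on toys", {
  # independent affine-gap NW oracle (match 1, mismatch -1; a gap of
  # length L costs open + L * ext with open 5, ext 1), scores only
  nw_score <- function(a, b, match = 1, mism = -1, open = 5, ext = 1) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b); NEG <- -1e9
    M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
    M[1, 1] <- 0
    for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
    for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mism
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  }
  cons <- paste(rep("ACGTTGCAGGATCCTA", 4), collapse = "")  # 64 bp
  set.seed(41)
  for (case in 1:5) {
    copy <- strsplit(cons, "")[[1]]
    copy[sample(64, 3)] <- sample(BASES4, 3, replace = TRUE)
    if (case > 2) copy <- copy[-sample(10:50, 1)]       # 1-bp deletion
    copy <- paste(copy, collapse = "")
    al <- suppressWarnings(align_to_consensus(copy, cons))
    expect_equal(al$score, nw_score(copy, cons))
  }
})

test_that("kmer_presence_matrix marks occurrence and annotates position", {
  tail40 <- strrep("CG", 20)
  seqs <- c(paste0("AAAAATCCATGAAAAACGCG", tail40),  # ATCCATG at 0-based 4
            paste0("AAAAAAAAAAAAAAAACGCG", tail40),
            paste0("ATCCATGATCCATGAAACGC", tail40))  # twice
  km <- kmer_presence_matrix(seqs, k = 7)
  expect_true("ATCCATG" %in% colnames(km$X))
  expect_equal(unname(km$X[, "ATCCATG"]), c(1L, 0L, 1L))
  # all columns occur somewhere; bound on the column count
  expect_true(all(colSums(km$X) >= 1))
  expect_lte(ncol(km$X), sum(nchar(seqs) - 6))
  # identical sequences give identical rows
  km2 <- kmer_presence_matrix(rep(seqs[1], 3), k = 7)
  expect_equal(km2$X[1, ], km2$X[2, ])
  # positional annotation via a trivial self-alignment
  km3 <- kmer_presence_matrix(seqs[1], k = 7,
                              alignment = align_to_consensus(seqs[1],
                                                             seqs[1]))
  expect_equal(unname(km3$positions[["ATCCATG"]]), 4)
})

test_that("logistic fit matches closed-form Woolf estimates on 2x2 tables
          (oracle grid)", {
  # Woolf: beta = log(ad/bc), se = sqrt(1/a + 1/b + 1/c + 1/d)
  grid <- expand.grid(a = c(10, 25, 60), b = c(90, 40),
                      c_ = c(30, 8), d = c(70, 120))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; c_ <- grid$c_[i]; d <- grid$d[i]
    presence <- rep(c(1, 1, 0, 0), c(a, b, c_, d))
    outcome <- rep(c(1, 0, 1, 0), c(a, b, c_, d))
    rec <- single_association(presence, outcome)
    beta_w <- log(a * d / (b * c_))
    se_w <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    expect_equal(rec$beta, beta_w, tolerance = 1e-3)
    expect_equal(rec$se, se_w, tolerance = 1e-3)
  }
  # frozen reference table: 10/90 hot among present, 30/70 among absent
  rec <- single_association(rep(c(1, 1, 0, 0), c(10, 90, 30, 70)),
                            rep(c(1, 0, 1, 0), c(10, 90, 30, 70)))
  expect_equal(rec$or, 0.2593, tolerance = 1e-3)
  expect_equal(rec$beta, -1.3499, tolerance = 1e-3)
  expect_equal(rec$se, 0.3984, tolerance = 1e-3)
})

test_that("null association p-values are calibrated and separation is
          flagged", {
  set.seed(43)
  pv <- vapply(1:40, function(i) {
    x <- rbinom(400, 1, 0.3)
    y <- rbinom(400, 1, 0.4)
    single_association(x, y)$p
  }, 0)
  expect_gt(mean(pv), 0.35)
  expect_lt(mean(pv), 0.65)
  expect_gt(mean(pv < 0.05), -0.01)  # sanity
  expect_lt(mean(pv < 0.05), 0.2)

  # complete separation: flagged, Firth fallback finite
  x <- rep(c(1, 0), each = 20)
  y <- rep(c(1, 0), each = 20)
  rec <- single_association(x, y)
  expect_true(rec$separated)
  expect_true(is.finite(rec$beta))
  expect_true(is.finite(rec$se))

  expect_error(single_association(x, rep(1, 40)), "both classes")
})

test_that("forward selection finds planted effects, collapses shadows,
          and controls the family-wise error", {
  set.seed(47)
  n <- 1500
  # causal k-mer + 3 perfectly-linked shadows + 60 noise columns
  causal <- rbinom(n, 1, 0.4)
  X <- cbind(matrix(rbinom(n * 60, 1, 0.3), n), causal, causal, causal,
             causal)
  colnames(X) <- c(replicate(60, paste(sample(BASES4, 7, TRUE),
                                       collapse = "")),
                   "AATTCCG", "ATTCCGG", "TTCCGGA", "TCCGGAA")
  X <- X[, !duplicated(colnames(X))]
  eta <- qlogis(0.3) + log(0.3) * causal
  y <- rbinom(n, 1, plogis(eta))
  km <- list(X = X, positions = setNames(c(rep(NA, ncol(X) - 4),
                                           10, 11, 12, 13),
                                         colnames(X)), k = 7)
  class(km) <- "KmerMatrix"
  sel <- forward_selection(km, y)
  expect_equal(nrow(sel), 1)
  expect_true(sel$kmer %in% c("AATTCCG", "ATTCCGG", "TTCCGGA", "TCCGGAA"))
  expect_lt(sel$beta, 0)
  # the three linked k-mers are recorded as shadows
  expect_equal(length(strsplit(sel$shadows, ",")[[1]]), 3)

  # two independent planted effects with opposite signs both selected
  x1 <- rbinom(n, 1, 0.4); x2 <- rbinom(n, 1, 0.4)
  X2 <- cbind(matrix(rbinom(n * 40, 1, 0.3), n), x1, x2)
  colnames(X2) <- c(replicate(40, paste(sample(BASES4, 7, TRUE),
                                        collapse = "")),
                    "AAAACCC", "GGGGTTT")
  X2 <- X2[, !duplicated(colnames(X2))]
  y2 <- rbinom(n, 1, plogis(qlogis(0.3) + log(0.32) * x1 + log(2) * x2))
  sel2 <- forward_selection(X2, y2)
  expect_true(all(c("AAAACCC", "GGGGTTT") %in% sel2$kmer))
  expect_lt(sel2$beta[sel2$kmer == "AAAACCC"], 0)
  expect_gt(sel2$beta[sel2$kmer == "GGGGTTT"], 0)

  # global null: nothing selected in the large majority of seeds
  hits <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rbinom(500 * 80, 1, 0.3), 500)
    colnames(Xn) <- paste0("k", seq_len(80))
    yn <- rbinom(500, 1, 0.35)
    nrow(forward_selection(Xn, yn))
  }, 0L)
  expect_lte(mean(hits > 0), 0.07 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("additive score bins are order-invariant and track the outcome", {
  set.seed(53)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  X <- cbind(AAAACCC = x1, GGGGTTT = x2)
  y <- rbinom(n, 1, plogis(-1 + log(0.32) * x1 + log(3) * x2))
  sel <- forward_selection(X, y)
  sc <- additive_score(sel, X, y)
  expect_equal(length(sc$score), n)
  # order invariance
  sc_rev <- additive_score(sel[rev(seq_len(nrow(sel))), ], X, y)
  expect_equal(sc$score, sc_rev$score)
  # per-bin outcome frequency increases with the bin score
  expect_gt(cor(sc$bins$mean_score, sc$bins$freq), 0.8)
  # single motif: two score levels {0, beta}
  sc1 <- additive_score(sel[sel$kmer == "AAAACCC", ], X)
  expect_equal(sort(unique(round(sc1$score, 6))),
               sort(unique(round(c(0, sel$beta[sel$kmer == "AAAACCC"]),
                                 6))))
  expect_warning(additive_score(sel[1, ], X * 0), "identical")
})

test_that("cobinding_glm reports log2-odds with the instance filter", {
  set.seed(59)
  n <- 3000
  f1 <- rbinom(n, 1, 0.2)               # plenty of instances
  f2 <- c(rep(1, 29), rep(0, n - 29))   # 29 instances: excluded
  # planted twofold local reduction in hotspot odds at f1 sites
  y <- rbinom(n, 1, plogis(qlogis(0.4) + log(0.5) * f1))
  res <- cobinding_glm(y, list(T28 = f1, Z282 = f2))
  expect_equal(res$factor, "T28")
  expect_lt(abs(res$log2_odds - (-1)), res$log2_odds - res$lo)
  # exact unit conversion: beta = -log(2) on the natural scale is -1 log2
  rec <- single_association(f1, y)
  expect_equal(res$log2_odds, rec$beta / log(2))
})
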