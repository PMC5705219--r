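## Synthetic genomes, ChIP fragments, repeat families and outcome labels
## with a recorded truth table, so every downstream stage can be tested
## against known ground truth.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults define
#' the reference study conditions used throughout the test-suite: a 5 Mb
#' single-chromosome genome with GC varying by block and one triploid block
#' (emulating aneuploidy), two ChIP replicates of unequal depth plus an
#' input control, planted two-half-site binding motifs with internal spacers
#' of 2, 5 or 6 bp, and a 354-bp repeat family carrying a planted binding
#' motif and a 7-bp modifier whose presence multiplies hotspot odds by
#' `or_mod` (default 0.32).
#'
#' @param genome_length Genome length in bp (single sequence named `chr1`).
#' @param block_length Length of GC/ploidy blocks in bp.
#' @param gc_blocks GC fraction per block, recycled across the genome.
#' @param ploidy_blocks Copy-number multiplier per block, recycled.
#' @param depth_chip1,depth_chip2,depth_input Expected fragment starts per
#'   base for the two ChIP replicates and the input control.
#' @param frag_mean,frag_sd Fragment length Normal(mean, sd), truncated to
#'   `[50, 1000]`.
#' @param lambda Enrichment scale: fragment start rate at an occupied site
#'   is multiplied by `1 + lambda * occupancy`.
#' @param n_sites Number of planted binding sites.
#' @param spacer_probs Probabilities of internal spacers of 2, 5 and 6 bp.
#' @param occupancy_a,occupancy_b Occupancy curve
#'   `plogis(occupancy_a * (score - occupancy_b))` applied to the planted
#'   instance's PWM log-odds score. By default `occupancy_b` sits 6
#'   log-units below the perfect-instance score, so perfect instances are
#'   ~0.998 occupied and one-mismatch instances ~0.94.
#' @param n_copies Number of repeat copies.
#' @param consensus_length Repeat consensus length in bp.
#' @param mu Per-base substitution rate applied to each repeat copy.
#' @param indel_prob Probability that a copy carries one 1-bp indel.
#' @param modifier Modifier k-mer planted in the repeat family.
#' @param p_mod Fraction of copies in which the modifier site is retained.
#' @param p_motif Fraction of copies in which the binding motif is planted.
#' @param or_mod Odds ratio on hotspot occurrence for modifier presence.
#' @param or_bind Odds ratio on hotspot occurrence for a bound copy.
#' @param p_hot_base Baseline hotspot probability (unbound, no modifier).
#' @param bind_a,bind_b Binding curve `plogis(bind_a * (score - bind_b))`
#'   mapping a copy's motif-match log-odds score to binding probability.
#' @param seed Integer random seed recorded with all outputs.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(genome_length = 5e6,
                       block_length = 1e6,
                       gc_blocks = c(0.38, 0.52, 0.45, 0.58, 0.40),
                       ploidy_blocks = c(1, 1, 3, 1, 1),
                       depth_chip1 = 0.08, depth_chip2 = 0.04,
                       depth_input = 0.08,
                       frag_mean = 250, frag_sd = 50,
                       lambda = 4, n_sites = 300,
                       spacer_probs = c(`2` = 0.5, `5` = 0.3, `6` = 0.2),
                       occupancy_a = 1, occupancy_b = NULL,
                       n_copies = 3000, consensus_length = 354,
                       mu = 0.03, indel_prob = 0.05,
                       modifier = "ATCCATG", p_mod = 0.4, p_motif = 0.5,
                       or_mod = 0.32, or_bind = 5, p_hot_base = 0.15,
                       bind_a = 0.8, bind_b = 10,
                       seed = 1L) {
  stopifnot(depth_chip1 > 0, depth_chip2 > 0, depth_input > 0,
            mu >= 0, mu < 1, or_mod > 0, or_bind > 0,
            abs(sum(spacer_probs) - 1) < 1e-9)
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

## RNG hygiene: run expr with a deterministic local seed, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

## Order-1 Markov background with persistence rho: next base copies the
## previous base with probability rho, otherwise is an iid draw from the
## block's base composition. This mixture form samples in vector time.
markov_background <- function(n, gc, rho = 0.1) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  iid <- sample.int(4L, n, replace = TRUE, prob = p)
  copy <- c(FALSE, runif(n - 1) < rho)
  idx <- cummax(seq_len(n) * (!copy))   # index of last fresh draw
  iid[idx]
}

## Two half-site truth PWMs used for planting. Columns are base
## probabilities with a 0.9 dominant base.
truth_half_sites <- function() {
  mk <- function(s) {
    m <- matrix(0.1 / 3, nrow = nchar(s), ncol = 4,
                dimnames = list(NULL, BASES))
    for (i in seq_len(nchar(s))) m[i, substr(s, i, i)] <- 0.9
    m
  }
  list(left = mk("CCTCCCT"), right = mk("AGCCATC"))
}

## Truth PWM for a given spacer width: left half, weakly specific spacer,
## right half. The internal spacing region carries a weak pyrimidine
## (T-leaning) base preference rather than uniform noise, mirroring the
## low-but-nonzero information content of the variably spaced region in
## real zinc-finger binding logos (the published hotspot 13-mer's wobble
## positions are C/T); without any preference the spacing variants are
## information-theoretically indistinguishable at sub-motif widths, and a
## preference matching the composition of the flanking half-sites blends
## into them.
truth_pwm <- function(spacer) {
  hs <- truth_half_sites()
  rbind(hs$left,
        matrix(rep(c(A = 0.15, C = 0.25, G = 0.15, T = 0.45),
                   each = spacer),
               nrow = spacer, ncol = 4, dimnames = list(NULL, BASES)),
        hs$right)
}

pwm_sample <- function(pwm) {
  vapply(seq_len(nrow(pwm)),
         function(i) sample.int(4L, 1L, prob = pwm[i, ]), 1L)
}

pwm_logodds <- function(pwm, codes) {
  sum(log(pwm[cbind(seq_len(nrow(pwm)), codes)] / 0.25))
}

#' Simulate a genome with planted binding sites
#'
#' Generates an order-1 Markov background whose GC content varies by block,
#' then plants `n_sites` motif instances drawn from ground-truth PWMs: two
#' half-sites separated by a background spacer of 2, 5 or 6 bp (drawn with
#' `spacer_probs`), on a random strand. Each planted instance's occupancy is
#' `plogis(occupancy_a * (score - occupancy_b))` of its PWM log-odds score;
#' by default `occupancy_b` is set 2 log-units below the perfect-instance
#' score so that typical planted sites are close to fully occupied.
#'
#' @param cfg A [sim_config()].
#' @return A list with `seq` (named character vector of sequences),
#'   `genome` (a [genome_index()]) and `truth` (a truth table: `sites`
#'   data.frame plus the resolved `cfg`).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    L <- cfg$genome_length
    nblock <- ceiling(L / cfg$block_length)
    gc <- rep_len(cfg$gc_blocks, nblock)
    codes <- unlist(lapply(seq_len(nblock), function(b) {
      len <- min(cfg$block_length, L - (b - 1) * cfg$block_length)
      markov_background(len, gc[b])
    }), use.names = FALSE)

    sites <- NULL
    if (cfg$n_sites > 0) {
      spacers <- as.integer(names(cfg$spacer_probs))
      motif_len_max <- 14 + max(spacers)
      if (motif_len_max > L) stop("motif longer than genome")
      ## evenly spaced site starts with random jitter; keeps sites apart
      slots <- floor(seq(2000, L - 2000 - motif_len_max,
                         length.out = cfg$n_sites))
      jitter <- sample.int(500, cfg$n_sites, replace = TRUE) - 250
      starts <- pmin(pmax(slots + jitter, 1000), L - 1000 - motif_len_max)
      variant <- sample(spacers, cfg$n_sites, replace = TRUE,
                        prob = cfg$spacer_probs)
      strand <- sample(c("+", "-"), cfg$n_sites, replace = TRUE)
      occ <- numeric(cfg$n_sites)
      score <- numeric(cfg$n_sites)
      width <- integer(cfg$n_sites)
      for (i in seq_len(cfg$n_sites)) {
        pwm <- truth_pwm(variant[i])
        inst <- pwm_sample(pwm)
        score[i] <- pwm_logodds(pwm, inst)
        b <- if (is.null(cfg$occupancy_b))
          pwm_logodds(pwm, apply(pwm, 1, which.max)) - 6 else cfg$occupancy_b
        occ[i] <- plogis(cfg$occupancy_a * (score[i] - b))
        if (strand[i] == "-") inst <- rev(5L - inst)
        codes[starts[i] + seq_along(inst)] <- inst   # 0-based start
        width[i] <- length(inst)
      }
      sites <- data.frame(chrom = "chr1", start = starts,
                          end = starts + width,
                          center = starts + floor(width / 2),
                          motif = paste0("spacer", variant),
                          spacing = variant, strand = strand,
                          score = score, occupancy = occ,
                          stringsAsFactors = FALSE)
    } else {
      sites <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), center = numeric(),
                          motif = character(), spacing = integer(),
                          strand = character(), score = numeric(),
                          occupancy = numeric(), stringsAsFactors = FALSE)
    }
    seq <- paste(BASES[codes], collapse = "")
    names(seq) <- "chr1"
    list(seq = seq, genome = genome_index(c(chr1 = L)),
         truth = list(sites = sites, cfg = cfg))
  })
}

## per-base ploidy multiplier vector for a genome of length L
ploidy_vector <- function(cfg, L) {
  nblock <- ceiling(L / cfg$block_length)
  mult <- rep_len(cfg$ploidy_blocks, nblock)
  rep(mult, each = cfg$block_length, length.out = L)
}

## draw fragments from a per-base start-rate vector
draw_fragments <- function(rate, cfg, L) {
  counts <- rpois(length(rate), rate)
  starts <- rep.int(seq_along(counts) - 1, counts)
  n <- length(starts)
  len <- round(rnorm(n, cfg$frag_mean, cfg$frag_sd))
  len <- pmin(pmax(len, 50), 1000)
  end <- starts + len
  keep <- end <= L
  fragment_set(rep("chr1", sum(keep)), starts[keep], end[keep])
}

#' Simulate ChIP and input fragments over a genome with planted sites
#'
#' Fragment start positions are Poisson with per-base rate
#' `depth * ploidy * (1 + lambda * occupancy)` within half a mean fragment
#' length of a planted site (background rate elsewhere). Fragment lengths
#' are Normal(`frag_mean`, `frag_sd`) truncated to `[50, 1000]`. The input
#' control uses `lambda = 0`, so it sees ploidy but not binding. Draws are
#' consumed in fixed order (rep1, rep2, input), so equal seeds give
#' byte-identical output.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param cfg A [sim_config()].
#' @return A list of three [fragment_set()]s: `rep1`, `rep2`, `input`.
#' @export
simulate_chip <- function(truth, cfg = sim_config()) {
  with_seed(cfg$seed + 1L, {
    L <- cfg$genome_length
    ploidy <- ploidy_vector(cfg, L)
    enrich <- rep(1, L)
    if (nrow(truth$sites) > 0) {
      ## a fragment is enriched when the site lies within half a fragment
      ## length of its midpoint, i.e. start in [ctr - frag_mean, ctr];
      ## this keeps the coverage apex centered on the planted site
      for (i in seq_len(nrow(truth$sites))) {
        ctr <- truth$sites$center[i]
        idx <- max(1, ctr - cfg$frag_mean + 1):min(L, ctr + 1)
        enrich[idx] <- pmax(enrich[idx],
                            1 + cfg$lambda * truth$sites$occupancy[i])
      }
    }
    rep1 <- draw_fragments(cfg$depth_chip1 * ploidy * enrich, cfg, L)
    rep2 <- draw_fragments(cfg$depth_chip2 * ploidy * enrich, cfg, L)
    input <- draw_fragments(cfg$depth_input * ploidy, cfg, L)
    list(rep1 = rep1, rep2 = rep2, input = input)
  })
}

## build the repeat-family consensus: background sequence with the binding
## motif (left half + 5 bp spacer + right half) at a fixed window and the
## modifier k-mer at a fixed position.
repeat_consensus <- function(cfg) {
  codes <- markov_background(cfg$consensus_length, 0.45)
  pwm <- truth_pwm(5L)
  motif <- apply(pwm, 1, which.max)
  codes[80 + seq_along(motif)] <- motif           # window [80, 99) 0-based
  modc <- match(strsplit(cfg$modifier, "")[[1]], BASES)
  codes[200 + seq_along(modc)] <- modc            # window [200, 207)
  list(codes = codes, motif_start = 80L, motif_len = length(motif),
       modifier_start = 200L, pwm = pwm)
}

#' Simulate a repeat family with planted motifs and outcome labels
#'
#' Each copy is the family consensus perturbed by iid substitutions at rate
#' `mu` and rare 1-bp indels. The binding motif is planted in a fixed
#' consensus window in a fraction `p_motif` of copies (the window is
#' replaced by background in the rest); the modifier k-mer site is retained
#' in a fraction `p_mod` and ablated otherwise. Binding is Bernoulli in the
#' logistic of the copy's motif-window PWM log-odds score, and the hotspot
#' outcome follows `logit P(hot) = qlogis(p_hot_base) + log(or_bind)*bound
#' + log(or_mod)*modifier`, where `modifier` is the realized presence of
#' the modifier k-mer anywhere in the copy's final sequence.
#'
#' @param cfg A [sim_config()].
#' @return A list with `copies` (data.frame of class `RepeatCopySet`:
#'   id, genomic interval, strand, oriented sequence, flags and outcomes),
#'   `consensus` (consensus sequence string) and `truth` (per-copy truth
#'   plus the resolved `cfg`).
#' @export
simulate_repeat_family <- function(cfg = sim_config()) {
  with_seed(cfg$seed + 2L, {
    if (cfg$consensus_length < 50) stop("consensus too short")
    cons <- repeat_consensus(cfg)
    n <- cfg$n_copies
    L <- cfg$consensus_length
    mat <- matrix(rep(cons$codes, n), nrow = n, byrow = TRUE)

    ## motif planting / knockout
    has_motif <- runif(n) < cfg$p_motif
    widx <- cons$motif_start + seq_len(cons$motif_len)
    if (any(!has_motif))
      mat[!has_motif, widx] <- sample.int(4L, sum(!has_motif) * length(widx),
                                          replace = TRUE)
    ## modifier ablation: substitute the central base of the planted site
    mod_kept <- runif(n) < cfg$p_mod
    mpos <- cons$modifier_start + 4L
    if (any(!mod_kept)) {
      cur <- mat[!mod_kept, mpos]
      mat[!mod_kept, mpos] <- 1L + (cur + sample.int(3L, sum(!mod_kept),
                                                     replace = TRUE) - 1L) %% 4L
    }
    ## iid substitutions at rate mu
    hit <- matrix(runif(n * L) < cfg$mu, nrow = n)
    nhit <- sum(hit)
    if (nhit > 0)
      mat[hit] <- 1L + (mat[hit] + sample.int(3L, nhit, replace = TRUE)
                        - 1L) %% 4L

    ## motif-window score and binding
    sub <- mat[, widx, drop = FALSE]
    lo <- log(t(apply(sub, 1, function(cc)
      cons$pwm[cbind(seq_along(cc), cc)])) / 0.25)
    score <- rowSums(lo)
    bound <- runif(n) < plogis(cfg$bind_a * (score - cfg$bind_b))

    seqs <- apply(mat, 1, function(cc) paste(BASES[cc], collapse = ""))

    ## rare 1-bp indels, applied at string level
    indel <- runif(n) < cfg$indel_prob
    if (any(indel)) {
      for (i in which(indel)) {
        pos <- sample.int(nchar(seqs[i]) - 1L, 1L)
        if (runif(1) < 0.5) {                     # deletion
          seqs[i] <- paste0(substr(seqs[i], 1, pos - 1),
                            substr(seqs[i], pos + 1, nchar(seqs[i])))
        } else {                                  # insertion
          seqs[i] <- paste0(substr(seqs[i], 1, pos),
                            sample(BASES, 1L),
                            substr(seqs[i], pos + 1, nchar(seqs[i])))
        }
      }
    }

    mod_present <- grepl(cfg$modifier, seqs, fixed = TRUE)
    eta <- qlogis(cfg$p_hot_base) + log(cfg$or_bind) * bound +
      log(cfg$or_mod) * mod_present
    hot <- runif(n) < plogis(eta)

    start <- (seq_len(n) - 1) * (L + 200) + 100
    strand <- sample(c("+", "-"), n, replace = TRUE)
    copies <- data.frame(id = sprintf("copy%05d", seq_len(n)),
                         chrom = "chrR", start = start,
                         end = start + nchar(seqs), strand = strand,
                         seq = seqs, motif_planted = has_motif,
                         modifier_present = mod_present,
                         score = score, bound = bound, hotspot = hot,
                         stringsAsFactors = FALSE)
    class(copies) <- c("RepeatCopySet", "data.frame")
    list(copies = copies,
         consensus = paste(BASES[cons$codes], collapse = ""),
         truth = list(repeats = copies[, c("id", "motif_planted",
                                           "modifier_present", "score",
                                           "bound", "hotspot")],
                      motif_window = c(start = cons$motif_start,
                                       len = cons$motif_len),
                      modifier_start = cons$modifier_start,
                      cfg = cfg))
  })
}

#' Write simulation outputs to a directory
#'
#' Emits FASTA (genome), fragment BEDs, a truth TSV and a TOML dump of the
#' resolved configuration.
#'
#' @param sim Result of [simulate_genome()].
#' @param frags Result of [simulate_chip()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, frags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", chunk_string(sim$seq[["chr1"]], 70)), fa)
  files <- fa
  for (nm in names(frags)) {
    f <- file.path(dir, paste0(nm, ".bed"))
    write_fragments(frags[[nm]], f)
    files <- c(files, f)
  }
  tt <- file.path(dir, "truth_sites.tsv")
  write_header_tsv(sim$truth$sites, tt)
  cf <- file.path(dir, "sim_config.toml")
  write_sim_config(sim$truth$cfg, cf)
  invisible(c(files, tt, cf))
}

chunk_string <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1, n, by = width)
  substring(s, starts, pmin(starts + width - 1, n))
}

## TSV with a single '#'-prefixed header line, LF-terminated
write_header_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Dump a simulation config as TOML
#' @param cfg A [sim_config()].
#' @param path Output path.
#' @export
write_sim_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.character(v)) paste0("\"", v, "\"")
    else if (length(v) > 1)
      paste0("[", paste(format(unname(v), scientific = FALSE, trim = TRUE),
                        collapse = ", "), "]")
    else format(v, scientific = FALSE, trim = TRUE)
  }
  keep <- !vapply(cfg, is.null, TRUE)
  writeLines(c("[simulation]",
               paste0(names(cfg)[keep], " = ",
                      vapply(cfg[keep], fmt, ""))), path)
  invisible(path)
}
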