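## Per-base likelihood model of ChIP enrichment over local background.
##
## Model at one base: replicate fragment-coverage counts
##   x_s ~ Poisson(r_s * b * (1 + e)),  e >= 0 shared across replicates,
## where b is the local background (input) rate and r_s the sample/input
## library-size ratio. The MLE has closed form
##   e_hat = max(0, sum(x) / (b * sum(r)) - 1),
## the one-sided test uses the chi-square(1) boundary mixture
## (0.5 * delta_0 + 0.5 * chisq_1), and the CI is the profile-likelihood
## interval at a deviance drop of 3.84, truncated at 0.

#' Estimate local background from an input coverage track
#'
#' The background rate at base `i` is the mean input coverage in a window of
#' width `W_bg` centered on `i` (truncated at chromosome edges). A plain
#' window mean absorbs regional coverage differences such as aneuploidy
#' blocks. Scale factors `r_s` are ratios of each sample's total fragments
#' to the input's.
#'
#' @param input_track Input/total-chromatin [coverage_track()].
#' @param W_bg Background window width in bp (>= 1000).
#' @param sample_totals Named numeric vector of sample fragment totals used
#'   to compute scale factors (optional; can be supplied later).
#' @return An object of class `BackgroundEstimate`: per-sequence background
#'   vectors `b`, window width, input totals and scale factors.
#' @export
estimate_background <- function(input_track, W_bg = 10000,
                                sample_totals = NULL) {
  if (W_bg < 1000) stop("W_bg must be at least 1000 bp")
  b <- lapply(names(input_track$values), function(nm) {
    v <- input_track$values[[nm]]
    if (all(v == 0)) {
      warning("all-zero input on ", nm, "; background floored at ",
              "0.5/W_bg")
      return(rep(0.5 / W_bg, length(v)))
    }
    running_mean(v, W_bg)
  })
  names(b) <- names(input_track$values)
  r_s <- if (!is.null(sample_totals))
    sample_totals / input_track$n_fragments else NULL
  structure(list(b = b, W_bg = W_bg,
                 input_fragments = input_track$n_fragments,
                 input_mass = input_track$mass, r_s = r_s),
            class = "BackgroundEstimate")
}

## centered running mean with truncated windows at the edges
running_mean <- function(v, W) {
  n <- length(v)
  half <- floor(W / 2)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-base Poisson likelihood-ratio test for enrichment
#'
#' Vectorized over bases. Given replicate counts `x1`, `x2`, local
#' background `b` and scale factors `r`, computes the shared-enrichment MLE
#' `e_hat`, the LRT statistic and the one-sided boundary p-value
#' `0.5 * P(chisq_1 >= Lambda)` (p = 1 when `e_hat = 0`).
#'
#' @param x1,x2 Replicate fragment-coverage counts at each base.
#' @param b Background rate (must be positive; floor it first).
#' @param r Length-2 vector of scale factors `(r1, r2)`.
#' @param ci Also compute profile-likelihood 95% CIs (slower; per-element
#'   root finding). Default FALSE.
#' @return A data.frame with columns `e` (enrichment, floored at 0),
#'   `lambda` (LRT statistic), `p`, and with `ci = TRUE` also `e_lo`,
#'   `e_hi`.
#' @examples
#' base_test(30, 30, b = 10, r = c(1, 1))  # e = 2, Lambda = 120*log(3) - 80
#' @export
base_test <- function(x1, x2, b, r = c(1, 1), ci = FALSE) {
  if (any(b <= 0)) stop("background must be positive; floor it first")
  stopifnot(length(r) == 2)
  sx <- x1 + x2
  sr <- r[1] + r[2]
  e <- pmax(0, sx / (sr * b) - 1)
  ## Lambda = 2 * [ sx*log(1+e) - sr*b*e ]
  lambda <- 2 * (sx * log1p(e) - sr * b * e)
  lambda[e == 0] <- 0
  p <- ifelse(lambda > 0, 0.5 * pchisq(lambda, df = 1, lower.tail = FALSE),
              1)
  out <- data.frame(e = e, lambda = lambda, p = p)
  if (ci) {
    cis <- t(mapply(profile_ci_e, sx, sr * b, e))
    out$e_lo <- cis[, 1]
    out$e_hi <- cis[, 2]
  }
  out
}

## profile-likelihood CI for e at deviance drop `drop` (3.84 ~ 95%);
## m = sr * b so that loglik(e) = sx*log(1+e) - m*e (+ const)
profile_ci_e <- function(sx, m, ehat, drop = qchisq(0.95, 1)) {
  ll <- function(e) sx * log1p(e) - m * e
  target <- ll(ehat) - drop / 2
  g <- function(e) ll(e) - target
  lo <- 0
  if (ehat > 0 && g(0) < 0)
    lo <- uniroot(g, c(0, ehat), tol = 1e-8)$root
  hi <- ehat + 1
  while (g(hi) > 0) hi <- hi * 2 + 1
  hi <- uniroot(g, c(ehat, hi), tol = 1e-8)$root
  c(lo, hi)
}

#' Call enrichment peaks from two ChIP replicates and an input control
#'
#' Applies [base_test()] at every base, keeps bases with `p < alpha`, and
#' merges kept bases into peaks allowing internal gaps up to `merge_gap`
#' bp. The peak center is the base with the smallest p-value (leftmost on
#' ties); enrichment, profile CI and per-sample counts are reported at the
#' center.
#'
#' @param chip1,chip2 Replicate [coverage_track()]s.
#' @param input Input [coverage_track()].
#' @param alpha Per-base p-value threshold (default `1e-6`).
#' @param W_bg Background window width in bp.
#' @param merge_gap Maximum gap between significant bases merged into one
#'   peak (default 250 bp).
#' @param bg Optional precomputed [estimate_background()] result.
#' @return A `data.frame` of class `PeakSet` with columns chrom, start,
#'   end, center, p, e, e_lo, e_hi, x1, x2, y (input count at center).
#' @export
call_peaks <- function(chip1, chip2, input, alpha = 1e-6, W_bg = 10000,
                       merge_gap = 250, bg = NULL) {
  if (!identical(chip1$genome$lengths, input$genome$lengths))
    stop("tracks must share a genome")
  if (is.null(bg)) bg <- estimate_background(input, W_bg)
  r <- c(chip1$n_fragments, chip2$n_fragments) / input$n_fragments
  peaks <- list()
  for (nm in names(input$values)) {
    bvec <- pmax(bg$b[[nm]], 0.5 / bg$W_bg)
    x1 <- chip1$values[[nm]]
    x2 <- chip2$values[[nm]]
    bt <- base_test(x1, x2, bvec, r)
    sig <- which(bt$p < alpha)
    if (length(sig) == 0) next
    ir <- IRanges::reduce(IRanges::IRanges(start = sig, width = 1L),
                          min.gapwidth = merge_gap + 1L)
    st <- IRanges::start(ir); en <- IRanges::end(ir)
    ctr <- p_ctr <- numeric(length(st))
    for (j in seq_along(st)) {
      idx <- st[j]:en[j]
      ctr[j] <- idx[which.min(bt$p[idx])]   # leftmost minimum
      p_ctr[j] <- bt$p[ctr[j]]
    }
    cc <- base_test(x1[ctr], x2[ctr], bvec[ctr], r, ci = TRUE)
    peaks[[nm]] <- data.frame(chrom = nm, start = st - 1, end = en,
                              center = ctr - 1, p = p_ctr, e = cc$e,
                              e_lo = cc$e_lo, e_hi = cc$e_hi,
                              x1 = x1[ctr], x2 = x2[ctr],
                              y = input$values[[nm]][ctr],
                              stringsAsFactors = FALSE)
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               center = numeric(), p = numeric(), e = numeric(),
               e_lo = numeric(), e_hi = numeric(), x1 = numeric(),
               x2 = numeric(), y = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("PeakSet", "data.frame")
  out
}

#' Force-call enrichment in fixed windows
#'
#' Computes the same Poisson LRT as [base_test()] for predefined intervals,
#' using window-summed counts. Per-base coverage mass in the window is
#' converted to an approximate fragment count by dividing by the sample's
#' mean insert size, so the Poisson model applies on the fragment-count
#' scale. Results are flagged undefined when the window's input fragment
#' count is at or below `min_input` (default 5).
#'
#' @param intervals An [interval_set()] (e.g. 1 kb windows around peaks).
#' @param sample A [coverage_track()] for the sample being tested.
#' @param input The input [coverage_track()].
#' @param bg An [estimate_background()] result for the input.
#' @param min_input Minimum input fragment count for a defined result.
#' @return A data.frame of class `ForceCallSet`: interval columns plus
#'   `x` (sample fragments), `y_input` (input fragments), `e`, `p`,
#'   `defined`.
#' @export
force_call <- function(intervals, sample, input, bg = NULL,
                       min_input = 5) {
  if (is.null(bg)) bg <- estimate_background(input)
  gl <- sample$genome$lengths
  if (any(!(intervals$chrom %in% names(gl))) ||
      any(intervals$end > gl[intervals$chrom]))
    stop("interval outside genome")
  mean_insert_s <- sample$mass / sample$n_fragments
  mean_insert_i <- input$mass / input$n_fragments
  r <- sample$n_fragments / input$n_fragments
  n <- nrow(intervals)
  x <- y <- bsum <- numeric(n)
  for (i in seq_len(n)) {
    nm <- intervals$chrom[i]
    idx <- (intervals$start[i] + 1):intervals$end[i]
    x[i] <- sum(sample$values[[nm]][idx]) / mean_insert_s
    y[i] <- sum(input$values[[nm]][idx]) / mean_insert_i
    bsum[i] <- sum(pmax(bg$b[[nm]][idx], 0.5 / bg$W_bg)) / mean_insert_i
  }
  e <- pmax(0, x / (r * bsum) - 1)
  lambda <- 2 * (x * log1p(e) - r * bsum * e)
  lambda[e == 0] <- 0
  p <- ifelse(lambda > 0, 0.5 * pchisq(lambda, 1, lower.tail = FALSE), 1)
  out <- data.frame(chrom = intervals$chrom, start = intervals$start,
                    end = intervals$end, x = x, y_input = y, e = e, p = p,
                    defined = y > min_input, stringsAsFactors = FALSE)
  class(out) <- c("ForceCallSet", "data.frame")
  out
}

#' Split fragments into two pseudo-replicates
#'
#' Each fragment is assigned to one half by a fair coin; the union of the
#' two halves is the input set. Used to emulate two replicates for samples
#' sequenced once.
#'
#' @param frags A [fragment_set()].
#' @param seed Integer seed; equal seeds give identical splits.
#' @return A list of two [fragment_set()]s.
#' @export
pseudo_replicates <- function(frags, seed = 1L) {
  if (nrow(frags) < 2) stop("need at least 2 fragments")
  with_seed(seed, {
    coin <- runif(nrow(frags)) < 0.5
    list(fragment_set(frags$chrom[coin], frags$start[coin],
                      frags$end[coin]),
         fragment_set(frags$chrom[!coin], frags$start[!coin],
                      frags$end[!coin]))
  })
}

#' Filter peaks for motif discovery
#'
#' Applies the stringent pre-motif-discovery filters: `p < p_max`,
#' enrichment `> e_min`, enrichment CI width `<= ci_max`, no overlap with
#' annotated repeats, input count at the center between the 10th and 90th
#' percentile of all peaks, and at least `min_reads` combined replicate
#' reads at the center. Survivors are ranked by decreasing enrichment and
#' the top `top_n` retained.
#'
#' @param peaks A `PeakSet` from [call_peaks()].
#' @param repeats Optional [interval_set()] of annotated repeats.
#' @param p_max,e_min,ci_max,min_reads,top_n Filter thresholds (defaults
#'   `1e-10`, 2, 50, 30, 5000).
#' @return The filtered, enrichment-ranked `PeakSet`.
#' @export
filter_peaks_for_motifs <- function(peaks, repeats = NULL, p_max = 1e-10,
                                    e_min = 2, ci_max = 50,
                                    min_reads = 30, top_n = 5000) {
  keep <- peaks$p < p_max & peaks$e > e_min &
    (peaks$e_hi - peaks$e_lo) <= ci_max &
    (peaks$x1 + peaks$x2) >= min_reads
  qy <- quantile(peaks$y, c(0.1, 0.9), names = FALSE)
  keep <- keep & peaks$y >= qy[1] & peaks$y <= qy[2]
  if (!is.null(repeats) && nrow(repeats) > 0) {
    ov <- vapply(seq_len(nrow(peaks)), function(i) {
      sel <- repeats$chrom == peaks$chrom[i]
      any(repeats$start[sel] < peaks$end[i] &
            repeats$end[sel] > peaks$start[i])
    }, TRUE)
    keep <- keep & !ov
  }
  out <- peaks[which(keep), , drop = FALSE]
  out <- out[order(-out$e), , drop = FALSE]
  out <- head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("PeakSet", "data.frame")
  out
}

#' Write a peak table as TSV
#'
#' Tab-separated, LF-terminated, single `#` header line; columns chrom,
#' start, end, center, p, e, e_lo, e_hi, x1, x2, y.
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  write_header_tsv(as.data.frame(peaks), path)
}
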