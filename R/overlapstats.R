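## Chance-corrected overlap statistics between genomic feature sets.
##
## For n single-base query points dropped uniformly on a genome of size g,
## the expected number of the t target intervals (widths w_i) overlapped by
## chance is
##     c = sum_i ( 1 - ((g - w_i) / g)^n ),
## and given f observed overlaps the corrected overlap fraction solves
##     (1 - f/t) = (1 - o/t)(1 - c/t)   =>   o/t = 1 - (1 - f/t)/(1 - c/t).

#' Expected number of chance overlaps between points and intervals
#'
#' Closed-form expectation of the number of target intervals overlapped by
#' at least one of `n` uniformly placed single-base query points. Evaluated
#' with `log1p` so it is stable for very large `n`.
#'
#' @param targets An [interval_set()], or a numeric vector of interval
#'   widths in bp.
#' @param n Number of query points.
#' @param g Genome size in bp.
#' @return Expected chance overlap count `c`.
#' @examples
#' expected_chance_overlaps(10, n = 2, g = 100)   # 1 - 0.9^2 = 0.19
#' @export
expected_chance_overlaps <- function(targets, n, g) {
  w <- if (inherits(targets, "data.frame")) targets$width else targets
  if (any(w > g)) stop("interval width exceeds genome size")
  if (n < 0) stop("n must be non-negative")
  if (n == 0 || length(w) == 0) return(0)
  sum(1 - exp(n * log1p(-w / g)))
}

#' Corrected overlap fraction
#'
#' Removes the chance component from an observed overlap fraction:
#' `o/t = 1 - (1 - f/t) / (1 - c/t)`. The correction is only reliable when
#' the chance overlaps are fewer than the observed overlaps (`c < f`); the
#' result carries a `valid` attribute recording that check.
#'
#' @param f Observed overlap count.
#' @param c Expected chance overlap count (from
#'   [expected_chance_overlaps()] or [shift_chance_overlaps()]).
#' @param t Number of target intervals.
#' @return The corrected overlap fraction `o/t` (raw, unclamped), with
#'   attribute `valid` (`TRUE` iff `c < f` and `c < t`).
#' @examples
#' corrected_overlap_fraction(0.81 * 100, 0.06 * 100, 100)  # ~0.798
#' @export
corrected_overlap_fraction <- function(f, c, t) {
  if (c >= t) stop("chance overlap count c >= t: correction undefined")
  o_t <- 1 - (1 - f / t) / (1 - c / t)
  attr(o_t, "valid") <- c < f
  o_t
}

#' Shift-based chance overlap estimate
#'
#' Estimates chance overlaps empirically by randomly shifting one interval
#' set and re-counting overlaps. Per replicate, every interval of `setB` is
#' shifted by a uniform integer draw in `[-shift_range, shift_range]`
#' (`per = "interval"`: one draw per interval; `per = "set"`: one draw for
#' the whole set); shifted intervals leaving their sequence are discarded
#' for that replicate. The count per replicate is the number of `setA`
#' (target) intervals overlapped by at least one shifted `setB` interval.
#'
#' @param setA Target [interval_set()].
#' @param setB Query [interval_set()] (the one shifted).
#' @param genome A [genome_index()] providing sequence bounds.
#' @param shift_range Maximum absolute shift in bp (default 60000).
#' @param reps Number of shift replicates (default 100).
#' @param seed Integer seed.
#' @param per `"interval"` (default) or `"set"` shifting.
#' @return A list with `c` (mean count across replicates), `se` (standard
#'   error of the mean) and `counts` (per-replicate counts).
#' @export
shift_chance_overlaps <- function(setA, setB, genome, shift_range = 60000,
                                  reps = 100, seed = 1L,
                                  per = c("interval", "set")) {
  per <- match.arg(per)
  stopifnot(reps >= 1)
  if (nrow(setB) == 0 || nrow(setA) == 0)
    return(list(c = 0, se = 0, counts = rep(0, reps)))
  lens <- genome$lengths
  with_seed(seed, {
    counts <- vapply(seq_len(reps), function(rep) {
      d <- if (per == "interval")
        sample.int(2 * shift_range + 1, nrow(setB), replace = TRUE) -
          shift_range - 1
      else
        rep(sample.int(2 * shift_range + 1, 1) - shift_range - 1,
            nrow(setB))
      s <- setB$start + d
      e <- setB$end + d
      ok <- s >= 0 & e <= lens[setB$chrom]
      count_overlapped_targets(setA, setB$chrom[ok], s[ok], e[ok])
    }, 0)
    list(c = mean(counts),
         se = sd(counts) / sqrt(reps),
         counts = counts)
  })
}

## number of target intervals intersected by >= 1 query interval
count_overlapped_targets <- function(targets, qchrom, qstart, qend) {
  total <- 0L
  for (nm in unique(targets$chrom)) {
    ts <- targets$chrom == nm
    qs <- qchrom == nm
    if (!any(qs)) next
    ta <- IRanges::IRanges(start = targets$start[ts] + 1,
                           end = targets$end[ts])
    qa <- IRanges::IRanges(start = qstart[qs] + 1, end = qend[qs])
    total <- total + sum(IRanges::countOverlaps(ta, qa) > 0)
  }
  total
}

#' Chance-corrected overlap summary between peak centers and targets
#'
#' Convenience wrapper: counts the target intervals containing at least one
#' query point, computes the analytic chance expectation and the corrected
#' overlap fraction.
#'
#' @param points Numeric vector of query point positions, or an
#'   [interval_set()] whose records carry a `center` column (e.g. a
#'   `PeakSet`); points pair with targets by sequence name when both carry
#'   `chrom`.
#' @param targets Target [interval_set()].
#' @param g Genome size in bp.
#' @return A data.frame of class `OverlapSummary` with n, t, f, c, f_t,
#'   c_t, o_t and `valid`.
#' @export
overlap_summary <- function(points, targets, g) {
  if (is.data.frame(points)) {
    pchrom <- points$chrom
    ppos <- if (!is.null(points$center)) points$center
            else floor((points$start + points$end) / 2)
  } else {
    pchrom <- rep(targets$chrom[1], length(points))
    ppos <- points
  }
  n <- length(ppos)
  t <- nrow(targets)
  f <- 0L
  for (nm in unique(targets$chrom)) {
    ts <- which(targets$chrom == nm)
    pp <- ppos[pchrom == nm]
    if (length(pp) == 0) next
    f <- f + sum(vapply(ts, function(i)
      any(pp >= targets$start[i] & pp < targets$end[i]), TRUE))
  }
  c <- expected_chance_overlaps(targets, n, g)
  o_t <- corrected_overlap_fraction(f, c, t)
  out <- data.frame(n = n, t = t, f = f, c = c, f_t = f / t, c_t = c / t,
                    o_t = as.numeric(o_t), valid = attr(o_t, "valid"))
  class(out) <- c("OverlapSummary", "data.frame")
  out
}
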