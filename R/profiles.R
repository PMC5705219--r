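## Aggregate signal profiles around anchor positions, quartile
## stratification, kernel smoothing and ratio profiles.

#' Aggregate a coverage track around anchor positions
#'
#' Computes, for each offset in `[-halfwidth, halfwidth]`, the mean track
#' value over anchors at `anchor + offset`. Anchors on the minus strand are
#' mirrored (their windows are reversed) when `mirror = TRUE`. Anchors
#' whose window would leave the sequence are dropped with a message.
#'
#' @param track A [coverage_track()].
#' @param anchors Data frame with `chrom`, `pos` (0-based) and optionally
#'   `strand` columns, or a numeric vector of positions on the track's
#'   first sequence.
#' @param halfwidth Half window width in bp.
#' @param mirror Mirror minus-strand anchors (default TRUE when a strand
#'   column is present).
#' @return A data.frame of class `Profile` with columns `offset`, `mean`,
#'   `se`, and attribute `n_anchors`.
#' @export
aggregate_profile <- function(track, anchors, halfwidth, mirror = NULL) {
  if (!is.data.frame(anchors))
    anchors <- data.frame(chrom = names(track$values)[1], pos = anchors,
                          strand = "*", stringsAsFactors = FALSE)
  if (is.null(anchors$strand)) anchors$strand <- "*"
  if (is.null(mirror)) mirror <- any(anchors$strand %in% c("+", "-"))
  lens <- track$genome$lengths
  ok <- anchors$pos - halfwidth >= 0 &
    anchors$pos + halfwidth < lens[anchors$chrom]
  if (any(!ok)) message(sum(!ok), " anchor(s) clipped at sequence edge")
  anchors <- anchors[ok, , drop = FALSE]
  if (nrow(anchors) == 0) stop("no valid anchors")
  offsets <- -halfwidth:halfwidth
  acc <- matrix(0, nrow = nrow(anchors), ncol = length(offsets))
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    win <- v[(anchors$pos[i] + 1 - halfwidth):(anchors$pos[i] + 1 +
                                                 halfwidth)]
    if (mirror && anchors$strand[i] == "-") win <- rev(win)
    acc[i, ] <- win
  }
  out <- data.frame(offset = offsets, mean = colMeans(acc),
                    se = apply(acc, 2, sd) / sqrt(nrow(acc)))
  attr(out, "n_anchors") <- nrow(anchors)
  class(out) <- c("Profile", "data.frame")
  out
}

#' Stratify peaks into quartiles of a key
#'
#' Quartile boundaries are the empirical 25/50/75 percentiles of the key;
#' ties on a boundary are assigned to the lower quartile. When all key
#' values are equal, everything lands in quartile 1 with a warning.
#'
#' @param peaks A data.frame (e.g. a `PeakSet`).
#' @param key Column name to stratify by (default `"e"`, the enrichment).
#' @return A list of four data.frames, lowest to highest quartile.
#' @export
stratify_by_quartile <- function(peaks, key = "e") {
  v <- peaks[[key]]
  if (length(v) < 4) stop("need at least 4 peaks")
  qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(v)) == 1)
    warning("all key values equal; everything in quartile 1")
  grp <- findInterval(v, qs, left.open = TRUE) + 1   # ties to lower
  lapply(1:4, function(q) peaks[grp == q, , drop = FALSE])
}

#' Kernel-smooth a profile
#'
#' Nadaraya-Watson smoothing via [stats::ksmooth()], whose kernels are
#' scaled so their quartiles sit at `+/- 0.25 * bandwidth` -- the
#' convention under which bandwidths like 25 or 200 bp are quoted. Edge
#' handling renormalizes over the available support.
#'
#' @param profile A `Profile` from [aggregate_profile()].
#' @param bandwidth Kernel bandwidth in bp.
#' @param kernel `"box"` (default) or `"normal"`.
#' @return A `Profile` with smoothed `mean`.
#' @export
smooth_profile <- function(profile, bandwidth, kernel = c("box", "normal")) {
  kernel <- match.arg(kernel)
  stopifnot(bandwidth > 0)
  span <- diff(range(profile$offset)) + 1
  if (bandwidth >= span) {
    warning("bandwidth >= profile span; returning the global mean")
    sm <- rep(mean(profile$mean), nrow(profile))
  } else {
    sm <- ksmooth(profile$offset, profile$mean, kernel = kernel,
                  bandwidth = bandwidth, x.points = profile$offset)$y
  }
  out <- profile
  out$mean <- sm
  out$se <- NULL
  out
}

#' Pointwise ratio of two profiles
#'
#' Divides the numerator profile by the denominator profile offset by
#' offset, flooring the denominator at `eps` (with a warning when the
#' floor engages). With `edge_normalize = TRUE`, the ratio is further
#' divided by its mean over the outer 10% of offsets on each side, so the
#' profile equals 1 at its edges.
#'
#' @param num,den `Profile` objects on identical offsets.
#' @param edge_normalize Normalize to 1 at the profile edges.
#' @param eps Denominator floor.
#' @return A `Profile` of ratios.
#' @export
ratio_profile <- function(num, den, edge_normalize = FALSE, eps = 1e-6) {
  stopifnot(identical(num$offset, den$offset))
  d <- den$mean
  if (any(d < eps)) {
    warning("denominator floored at eps")
    d <- pmax(d, eps)
  }
  ratio <- num$mean / d
  if (edge_normalize) {
    k <- max(1, floor(0.05 * length(ratio)))
    edge <- c(seq_len(k), length(ratio) - seq_len(k) + 1)
    ratio <- ratio / mean(ratio[edge])
  }
  out <- data.frame(offset = num$offset, mean = ratio)
  class(out) <- c("Profile", "data.frame")
  out
}

#' Write a profile as TSV
#' @param profile A `Profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  write_header_tsv(as.data.frame(profile), path)
}
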