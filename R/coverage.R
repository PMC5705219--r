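## Fragment sets and per-base coverage tracks.

#' Construct a fragment set
#'
#' Sequenced fragments as (sequence name, start, end) records in 0-based
#' half-open coordinates. Insert size is `end - start` and must be positive.
#'
#' @param chrom,start,end Vectors defining the fragments.
#' @param genome Optional [genome_index()] for bounds checking.
#' @return A `data.frame` of class `FragmentSet` with an `insert` column.
#' @export
fragment_set <- function(chrom, start, end, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("fragment with end <= start")
  if (!is.null(genome)) {
    if (!all(df$chrom %in% genome$names)) stop("unknown sequence name")
    if (any(df$start < 0 | df$end > genome$lengths[df$chrom]))
      stop("fragment outside genome bounds")
  }
  df$insert <- df$end - df$start
  class(df) <- c("FragmentSet", "data.frame")
  df
}

#' Read fragments from a BED-like file
#'
#' Parses a tab-separated file with at least three columns (sequence, start,
#' end; 0-based half-open). Malformed lines are an error naming the line
#' number. When a genome index is given, records on unknown sequences are an
#' error and records exceeding sequence bounds are dropped with a warning
#' giving the count.
#'
#' @param path Path to a fragment BED file.
#' @param genome Optional [genome_index()].
#' @return A [fragment_set()].
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t350", tf)
#' read_fragments(tf)
#' @export
read_fragments <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("parse error at line ", lineno[which(bad)[1]],
         ": non-integer coordinates")
  if (any(end <= start))
    stop("parse error at line ", lineno[which(end <= start)[1]],
         ": end <= start")
  if (!is.null(genome)) {
    unk <- !(chrom %in% genome$names)
    if (any(unk))
      stop("unknown sequence '", chrom[which(unk)[1]], "' at line ",
           lineno[which(unk)[1]])
    oob <- start < 0 | end > genome$lengths[chrom]
    if (any(oob)) {
      warning(sum(oob), " out-of-bounds fragment(s) dropped")
      chrom <- chrom[!oob]; start <- start[!oob]; end <- end[!oob]
    }
  }
  fragment_set(chrom, start, end)
}

#' Write fragments as BED3
#' @param frags A [fragment_set()].
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  write.table(data.frame(frags$chrom, format_coord(frags$start),
                         format_coord(frags$end)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Construct a coverage track
#'
#' Per-base non-negative coverage values over the sequences of a genome,
#' together with the sample label and the number of fragments that produced
#' the track (used downstream for library-size scale factors and for
#' converting window coverage mass back to fragment counts).
#'
#' @param values Named list of numeric vectors, one per sequence, lengths
#'   matching the genome index.
#' @param genome A [genome_index()].
#' @param sample Sample label.
#' @param n_fragments Total fragments behind the track.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(values, genome, sample = "sample",
                           n_fragments = NA_real_) {
  if (!identical(sort(names(values)), sort(genome$names)))
    stop("coverage sequences do not match genome index")
  for (nm in genome$names) {
    if (length(values[[nm]]) != genome$lengths[[nm]])
      stop("coverage length mismatch on ", nm)
    if (any(values[[nm]] < 0)) stop("negative coverage on ", nm)
  }
  mass <- sum(vapply(values, sum, 0))
  structure(list(values = values[genome$names], genome = genome,
                 sample = sample, n_fragments = n_fragments, mass = mass),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack '", x$sample, "': ", length(x$values),
      " sequence(s), total mass ", format(x$mass, big.mark = ","),
      if (!is.na(x$n_fragments))
        paste0(", ", format(x$n_fragments, big.mark = ","), " fragments"),
      "\n", sep = "")
  invisible(x)
}

#' Compute per-base fragment coverage
#'
#' The value at base `b` is the number of fragments whose `[start, end)`
#' interval contains `b`. An empty fragment set gives an all-zero track.
#' The total mass of the track equals the sum of insert sizes.
#'
#' @param frags A [fragment_set()].
#' @param genome A [genome_index()].
#' @param sample Sample label stored on the track.
#' @return A [coverage_track()].
#' @export
fragments_to_coverage <- function(frags, genome, sample = "sample") {
  if (any(!(frags$chrom %in% genome$names)) ||
      any(frags$start < 0 | frags$end > genome$lengths[frags$chrom]))
    stop("fragments outside genome bounds")
  values <- lapply(genome$names, function(nm) {
    L <- genome$lengths[[nm]]
    d <- numeric(L + 1)
    sel <- frags$chrom == nm
    if (any(sel)) {
      s <- frags$start[sel] + 1          # 1-based diff array
      e <- frags$end[sel] + 1
      add <- tabulate(s, nbins = L + 1)
      sub <- tabulate(e, nbins = L + 1)
      d <- add - sub
    }
    cumsum(d)[seq_len(L)]
  })
  names(values) <- genome$names
  coverage_track(values, genome, sample = sample, n_fragments = nrow(frags))
}

#' Classify ATAC-seq fragments by insert size
#'
#' Splits fragments into inter-nucleosome (insert size 51-100 bp) and
#' mono-nucleosome (180-247 bp) classes; all other fragments are dropped.
#' Downstream coverage for these classes uses the central base of each
#' fragment (for even insert sizes, the left of the two central bases).
#'
#' @param frags A [fragment_set()].
#' @return A list with elements `inter` and `mono`, each a [fragment_set()]
#'   carrying a `center` column (0-based position of the central base).
#' @export
classify_atac_fragments <- function(frags) {
  center <- floor((frags$start + frags$end - 1) / 2)
  pick <- function(sel) {
    out <- fragment_set(frags$chrom[sel], frags$start[sel], frags$end[sel])
    out$center <- center[sel]
    out
  }
  list(inter = pick(frags$insert >= 51 & frags$insert <= 100),
       mono = pick(frags$insert >= 180 & frags$insert <= 247))
}

#' Read a bedGraph file into a coverage track
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @param genome A [genome_index()]; bases not covered by any record are 0.
#' @param sample Sample label.
#' @param n_fragments Optional fragment count to attach.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, genome, sample = "sample",
                          n_fragments = NA_real_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  val <- as.numeric(vapply(fields, `[[`, "", 4L))
  values <- lapply(genome$names, function(nm) {
    v <- numeric(genome$lengths[[nm]])
    sel <- which(chrom == nm)
    for (i in sel) v[(start[i] + 1):end[i]] <- val[i]
    v
  })
  names(values) <- genome$names
  coverage_track(values, genome, sample = sample, n_fragments = n_fragments)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into single records; zero runs are kept
#' so that a read/write round trip is exact for integer tracks. Output is
#' tab-separated, LF-terminated, with one `#` header line.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param drop_zero Omit zero-valued runs (smaller files; default FALSE).
#' @export
write_bedgraph <- function(track, path, drop_zero = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#chrom\tstart\tend\tvalue sample=", track$sample), con)
  for (nm in names(track$values)) {
    v <- track$values[[nm]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(end))
    if (any(keep))
      writeLines(paste(nm, format_coord(start[keep]),
                       format_coord(end[keep]), r$values[keep],
                       sep = "\t"), con)
  }
  invisible(path)
}
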