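## Genomic coordinate model shared by all modules.
## Coordinates are 0-based half-open (BED convention) everywhere internally.

#' Genome index
#'
#' A minimal index of a genome: unique sequence names, their lengths, and the
#' total genome size `g` used by the overlap statistics.
#'
#' @param lengths Named integer vector of sequence lengths in bp.
#' @return An object of class `GenomeIndex` with elements `names`, `lengths`
#'   (named integer vector) and `g` (total length in bp).
#' @examples
#' gi <- genome_index(c(chr1 = 1e6, chr2 = 5e5))
#' gi$g
#' @export
genome_index <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("sequence lengths must be uniquely named")
  if (any(lengths <= 0)) stop("sequence lengths must be positive")
  lengths <- setNames(as.numeric(lengths), names(lengths))
  structure(list(names = names(lengths), lengths = lengths,
                 g = sum(lengths)),
            class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$names), "sequence(s),",
      format(x$g, big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a genome index from a FASTA index (.fai) file
#'
#' Only the first two columns (name, length) are used, as written by
#' `samtools faidx`.
#'
#' @param path Path to a tab-separated `.fai` file.
#' @return A [genome_index()] object.
#' @export
read_genome_index <- function(path) {
  fai <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  genome_index(setNames(as.numeric(fai[[2]]), fai[[1]]))
}

#' Build a genome index from sequences
#'
#' @param seqs A named character vector or `Biostrings::DNAStringSet`.
#' @return A [genome_index()] object.
#' @export
genome_index_from_seqs <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet"))
    return(genome_index(setNames(Biostrings::width(seqs), names(seqs))))
  genome_index(setNames(nchar(seqs), names(seqs)))
}

## ---- interval sets ---------------------------------------------------------

#' Construct an interval set
#'
#' Records of (sequence name, start, end) in 0-based half-open coordinates,
#' with optional strand and score, validated against a genome index when one
#' is supplied.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors, 0-based half-open; `start < end`.
#' @param strand Optional character vector in `+`, `-`, `*`.
#' @param score Optional numeric vector.
#' @param genome Optional [genome_index()]; bounds are checked against it.
#' @return A `data.frame` of class `IntervalSet` with a `width` column
#'   (`end - start`).
#' @export
interval_set <- function(chrom, start, end, strand = NULL, score = NULL,
                         genome = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start < 0")
  if (any(end <= start)) stop("interval end <= start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  df$strand <- if (is.null(strand)) rep("*", nrow(df))
               else as.character(strand)
  if (!is.null(score)) df$score <- score
  if (!is.null(genome)) {
    bad <- !(df$chrom %in% genome$names)
    if (any(bad)) stop("unknown sequence name(s): ",
                       paste(unique(df$chrom[bad]), collapse = ", "))
    if (any(df$end > genome$lengths[df$chrom]))
      stop("interval end beyond sequence length")
  }
  df$width <- df$end - df$start
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Read a BED3/BED6 file into an interval set
#'
#' Coordinates are kept exactly as read (BED is already 0-based half-open).
#' Lines beginning `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a BED file.
#' @param genome Optional [genome_index()] used to validate records;
#'   out-of-bounds records are dropped with a warning giving the count.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(interval_set(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  if (any(end <= start))
    stop("malformed BED line ", which(end <= start)[1], ": end <= start")
  strand <- if (all(nf >= 6)) vapply(fields, `[[`, "", 6L) else NULL
  score <- if (all(nf >= 5))
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))) else NULL
  if (!is.null(genome)) {
    ok <- chrom %in% genome$names & end <= genome$lengths[chrom] & start >= 0
    ok[is.na(ok)] <- FALSE
    if (any(!ok))
      warning(sum(!ok), " record(s) out of genome bounds dropped")
    chrom <- chrom[ok]; start <- start[ok]; end <- end[ok]
    strand <- strand[ok]; score <- score[ok]
  }
  interval_set(chrom, start, end, strand = strand, score = score)
}

#' Write an interval set as BED
#'
#' Writes BED6 when strand or score is informative, BED3 otherwise.
#' Coordinates pass through exactly; the half-open convention is never
#' shifted.
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  has6 <- any(x$strand != "*") || !is.null(x$score)
  if (has6) {
    score <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                      ".", score, x$strand)
  } else {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

## integer-exact coordinate formatting (avoids 1e+05 style output)
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
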