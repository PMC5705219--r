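# shared fixture builders: everything is generated in code at test time

BASES4 <- c("A", "C", "G", "T")

# iid random sequence(s) with a given GC fraction
random_seqs <- function(n, L, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(BASES4, L, replace = TRUE, prob = p), collapse = ""), "")
}

# plant a motif (random strand) near the center of a sequence
plant_motif <- function(s, motif, jitter = 20) {
  L <- nchar(s); M <- nchar(motif)
  pos <- round(L / 2 - M / 2) + sample(-jitter:jitter, 1)
  if (runif(1) < 0.5) motif <- revcomp_str(motif)
  paste0(substr(s, 1, pos), motif, substr(s, pos + M + 1, L))
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# sharp PWM for a consensus string (for truth comparisons)
consensus_pwm <- function(s, major = 0.98) {
  m <- matrix((1 - major) / 3, nchar(s), 4, dimnames = list(NULL, BASES4))
  for (i in seq_len(nchar(s))) m[i, substr(s, i, i)] <- major
  m
}

# write a small fragment BED and return its path
write_frag_file <- function(lines) {
  tf <- tempfile(fileext = ".bed")
  writeLines(lines, tf)
  tf
}

# constant-coverage track on a toy genome
flat_track <- function(value, L = 1000, n_fragments = 1000,
                       sample = "flat") {
  gi <- genome_index(c(chr1 = L))
  coverage_track(list(chr1 = rep(value, L)), gi, sample = sample,
                 n_fragments = n_fragments)
}
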