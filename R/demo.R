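## End-to-end demonstration pipeline on synthetic data:
## simulate -> call peaks -> discover motifs -> overlap statistics ->
## repeat-family association -> aggregate profile, with a manifest.

#' Run the full pipeline on synthetic data
#'
#' Simulates a genome with planted binding sites, two ChIP replicates and
#' an input control; calls peaks; discovers motifs in peak-centered
#' sequences; computes the chance-corrected overlap between peak centers
#' and windows around the planted sites; runs the repeat-family modifier
#' association; and writes an aggregate coverage profile. Every artifact
#' is written under `dir` and listed, with its md5 hash, in
#' `manifest.json`; the same config and seed give identical manifests.
#'
#' @param dir Output directory (must be creatable/writable).
#' @param cfg A [sim_config()]; the default scale finishes in minutes.
#' @param max_seeds Motif-seeding rounds for the demo (default 6).
#' @param verbose Print stage progress.
#' @return Invisibly, the manifest as a data.frame (file, md5).
#' @export
run_demo <- function(dir, cfg = sim_config(), max_seeds = 6,
                     verbose = TRUE) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("output directory not writable: ", dir)
  say <- function(...) if (verbose) message(format(Sys.time(),
                                                   "%Y-%m-%dT%H:%M:%S"),
                                            " [demo] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)

  say("simulate")
  sim <- stage("simulate", simulate_genome(cfg))
  frags <- stage("simulate", simulate_chip(sim$truth, cfg))
  files <- c(files, stage("simulate", write_simulation(sim, frags, dir)))

  say("coverage + callpeaks")
  peaks <- stage("callpeaks", {
    cov1 <- fragments_to_coverage(frags$rep1, sim$genome, "rep1")
    cov2 <- fragments_to_coverage(frags$rep2, sim$genome, "rep2")
    covi <- fragments_to_coverage(frags$input, sim$genome, "input")
    pk <- call_peaks(cov1, cov2, covi)
    f <- file.path(dir, "peaks.tsv")
    write_peaks(pk, f)
    files <- c(files, f)
    attr(pk, "input") <- covi
    pk
  })

  say("findmotifs (", nrow(peaks), " peaks)")
  stage("findmotifs", {
    seqs <- extract_peak_sequences(peaks, sim$seq)
    if (length(seqs) >= 100) {
      model <- discover_motifs(seqs, max_seeds = max_seeds)
      model <- filter_motifs(model, seqs)
      f <- file.path(dir, "motifs.meme")
      write_meme(model, f)
      files <- c(files, f)
      if (length(model$pwms) > 0) {
        mf <- file.path(dir, "matches.tsv")
        write_matches(force_scan(model, seqs), mf)
        files <- c(files, mf)
      }
    }
  })

  say("overlap")
  stage("overlap", {
    targets <- interval_set(sim$truth$sites$chrom,
                            pmax(sim$truth$sites$center - 500, 0),
                            sim$truth$sites$center + 500)
    ov <- overlap_summary(peaks, targets, sim$genome$g)
    f <- file.path(dir, "overlap.tsv")
    write_header_tsv(as.data.frame(ov), f)
    files <- c(files, f)
  })

  say("repeatassoc (", cfg$n_copies, " copies)")
  stage("repeatassoc", {
    fam <- simulate_repeat_family(cfg)
    aln <- align_to_consensus(fam$copies$seq, fam$consensus)
    km <- kmer_presence_matrix(fam$copies$seq, k = 7, alignment = aln)
    sel <- forward_selection(km, fam$copies$hotspot,
                             covariates = cbind(bound = fam$copies$bound),
                             max_terms = 5)
    f <- file.path(dir, "associations.tsv")
    write_associations(sel, f)
    files <- c(files, f)
    if (nrow(sel) > 0) {
      sc <- additive_score(sel, km, fam$copies$hotspot)
      f2 <- file.path(dir, "score_bins.tsv")
      write_header_tsv(sc$bins, f2)
      files <- c(files, f2)
    }
  })

  say("profile")
  stage("profile", {
    covi <- attr(peaks, "input")
    anchors <- data.frame(chrom = sim$truth$sites$chrom,
                          pos = sim$truth$sites$center,
                          strand = sim$truth$sites$strand)
    pr <- aggregate_profile(covi, anchors, halfwidth = 1000)
    pr <- smooth_profile(pr, bandwidth = 25)
    f <- file.path(dir, "profile.tsv")
    write_profile(pr, f)
    files <- c(files, f)
  })

  say("manifest")
  files <- unique(files)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(list(seed = cfg$seed, files = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
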