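# cached full-scale manifest: codebook search for 611 codes is the slow part,
# share one instance across test files
full_manifest <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gbdel_manifest(seed = 1)
    cache
  }
})

# independent Hamming distance between two equal-length strings
ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# independent O(n^2 L) pairwise minimum distance (oracle for codebook checks)
min_dist_oracle <- function(seqs) {
  n <- length(seqs)
  best <- Inf
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      best <- min(best, ham(seqs[i], seqs[j]))
  best
}

# simulate one sp-style selection on a toy grid and decode it
toy_selection <- function(manifest, a_id, b_id, fold, depth, seed,
                          error_rate = 0, max_mismatch = 0L) {
  truth <- ground_truth(manifest)
  truth <- plant_binder(truth, a_id, b_id, fold)
  cap <- simulate_capture(truth, seed = seed)
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(c(fq, paste0(fq, ".truth.tsv"))))
  res <- sequence_reads(cap, manifest,
                        sequencing_config(depth, error_rate, seed), fq)
  list(decoded = decode_fastq(fq, manifest, max_mismatch),
       true_counts = res$true_counts)
}
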