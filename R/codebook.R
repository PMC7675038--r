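#' Generate an error-correcting barcode codebook
#'
#' Seeded greedy random search for `n_codes` DNA sequences of fixed length
#' whose pairwise Hamming distance is at least `d_min`. With `d_min = 3` any
#' single substitution maps an observed code back to a unique codebook entry
#' (sphere packing), which is the error-correction contract the decoder
#' relies on.
#'
#' Candidates are drawn uniformly over the 4^`length` sequence space and
#' accepted when they keep the minimum distance; the search aborts once an
#' attempt budget proportional to `n_codes` is spent, which signals that the
#' requested code count is implausible at this length/distance.
#'
#' @param n_codes number of codes required.
#' @param length code length in nucleotides (default 8).
#' @param d_min minimum pairwise Hamming distance (default 3).
#' @param seed integer seed; the search is reproducible under a fixed seed.
#' @param role `"CodeA"` or `"CodeB"`; used for the `role` column and the
#'   default `code_id` prefix ("A"/"B").
#' @param prefix optional code-id prefix overriding the role-derived one.
#' @param attempt_budget maximum candidate draws (default `500 * n_codes`).
#' @return data.frame with columns `code_id`, `sequence`, `role`.
#' @export
#' @examples
#' cb <- generate_codebook(8, length = 6, d_min = 3, seed = 1)
#' codebook_min_distance(cb$sequence) # >= 3
generate_codebook <- function(n_codes, length = 8L, d_min = 3L, seed = 1L,
                              role = c("CodeA", "CodeB"), prefix = NULL,
                              attempt_budget = 500L * n_codes) {
  role <- match.arg(role)
  stopifnot(n_codes >= 1L, length >= 1L, d_min >= 1L, d_min <= length)
  prefix <- prefix %||% if (role == "CodeA") "A" else "B"
  acc <- matrix(0L, nrow = 0L, ncol = length)
  withr::with_seed(seed, {
    attempts <- 0L
    while (nrow(acc) < n_codes) {
      if (attempts >= attempt_budget)
        stop("codebook search exhausted ", attempt_budget, " attempts at ",
             nrow(acc), "/", n_codes, " codes; use longer codes or a ",
             "smaller d_min")
      cand <- sample.int(4L, length, replace = TRUE)
      attempts <- attempts + 1L
      if (nrow(acc) == 0L ||
          min(colSums(t(acc) != cand)) >= d_min)
        acc <- rbind(acc, cand)
    }
  })
  seqs <- apply(acc, 1L, function(r) paste(DNA_ALPHABET[r], collapse = ""))
  data.frame(code_id = paste0(prefix, seq_len(n_codes)),
             sequence = seqs, role = role, stringsAsFactors = FALSE)
}

#' Minimum pairwise Hamming distance of a set of sequences
#'
#' Independent O(n^2 L) verification used by manifest validation and in the
#' test-suite to audit generated codebooks.
#'
#' @param sequences character vector of equal-length DNA sequences.
#' @return the minimum pairwise Hamming distance (Inf for fewer than two
#'   sequences).
#' @export
codebook_min_distance <- function(sequences) {
  min_pairwise_hamming(sequences)$min
}
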