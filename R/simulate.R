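#' Ground truth for a simulated selection
#'
#' Defines the capture model for every library member: a baseline
#' per-molecule capture probability `base_capture_prob` (p0), a per-member
#' enrichment fold (>= 1, default 1 = background), and the number of input
#' copies per member (`copies_per_member`, the 1e7 molecules of each
#' compound that enter one selection aliquot). A member with fold f is
#' captured with probability min(1, p0 * f), so planted binders stand out
#' from background proportionally to their fold.
#'
#' @param manifest a `del_manifest`.
#' @param base_capture_prob baseline capture probability per molecule.
#' @param copies_per_member input copies of every member (default 1e7).
#' @return object of class `del_truth`: the member table with a `fold`
#'   column plus model parameters.
#' @seealso [plant_binder()], [simulate_capture()]
#' @export
ground_truth <- function(manifest, base_capture_prob = 1e-5,
                         copies_per_member = 1e7) {
  stopifnot(base_capture_prob > 0, base_capture_prob <= 1,
            copies_per_member >= 1)
  members <- enumerate_library(manifest)
  members$fold <- 1
  structure(list(members = members,
                 base_capture_prob = base_capture_prob,
                 copies_per_member = copies_per_member),
            class = "del_truth")
}

#' Plant a binder into the ground truth
#'
#' Assigns an enrichment fold to one (A, B) combination. By default both
#' stereoisomers receive the fold (chirality is not resolved during
#' selection); pass `stereo` to enrich a single isomer.
#'
#' @param truth a `del_truth`.
#' @param a_id,b_id the combination to enrich.
#' @param fold enrichment fold (>= 1).
#' @param stereo optional stereo label(s) to restrict the planting.
#' @return the updated `del_truth`.
#' @export
plant_binder <- function(truth, a_id, b_id, fold, stereo = NULL) {
  stopifnot(inherits(truth, "del_truth"), fold >= 1)
  sel <- truth$members$a_id == a_id & truth$members$b_id == b_id
  if (!is.null(stereo)) sel <- sel & truth$members$stereo %in% stereo
  if (!any(sel)) stop("no library member matches ", a_id, "/", b_id)
  truth$members$fold[sel] <- fold
  truth
}

#' Selection mode: single- or dual-pharmacophore
#'
#' SP is the plain single-stranded library selection; DP ("2+1") anneals
#' the library to a complementary oligonucleotide displaying a known
#' protein-binding moiety (`hit_label`), so building blocks that cooperate
#' with the hit gain an additional synergy multiplier on their capture
#' fold.
#'
#' @param mode `"SP"` or `"DP"`.
#' @param hit_label identifier of the complementary-strand moiety (required
#'   for DP).
#' @param multipliers data.frame `(a_id, b_id, multiplier)` of synergy
#'   multipliers (>= 1) applied on top of the SP fold in DP mode.
#' @return object of class `del_mode`.
#' @export
selection_mode <- function(mode = c("SP", "DP"), hit_label = NULL,
                           multipliers = NULL) {
  mode <- match.arg(mode)
  if (mode == "DP") {
    if (is.null(hit_label))
      stop("DP mode requires a hit_label for the complementary-strand moiety")
    if (!is.null(multipliers) && any(multipliers$multiplier < 1))
      stop("synergy multipliers must be >= 1")
  }
  structure(list(mode = mode, hit_label = hit_label,
                 multipliers = multipliers), class = "del_mode")
}

#' Sequencing configuration
#'
#' @param depth total reads to emit (the TCs scale of the run).
#' @param error_rate per-base substitution probability (substitutions only;
#'   the fixed-position read layout assumes no indels).
#' @param seed integer seed for the multinomial read draw and error
#'   injection.
#' @return object of class `del_seqcfg`.
#' @export
sequencing_config <- function(depth, error_rate = 0, seed = 1L) {
  stopifnot(depth >= 0, error_rate >= 0, error_rate < 1)
  structure(list(depth = as.integer(depth), error_rate = error_rate,
                 seed = as.integer(seed)), class = "del_seqcfg")
}

effective_folds <- function(truth, mode) {
  f <- truth$members$fold
  if (!is.null(mode) && mode$mode == "DP" && !is.null(mode$multipliers)) {
    key <- paste(truth$members$a_id, truth$members$b_id, sep = "|")
    mkey <- paste(mode$multipliers$a_id, mode$multipliers$b_id, sep = "|")
    i <- match(key, mkey)
    mult <- ifelse(is.na(i), 1, mode$multipliers$multiplier[i])
    f <- f * mult
  }
  f
}

#' Simulate affinity capture
#'
#' One round of bead capture: each member's captured molecule count is drawn
#' Binomial(copies_per_member, min(1, p0 * fold_eff)), where in DP mode
#' fold_eff is the SP fold times the synergy multiplier. Capture
#' probabilities that would exceed 1 are capped with a warning.
#'
#' @param truth a `del_truth`.
#' @param mode optional `del_mode` (default SP).
#' @param seed integer seed; fixed seed gives identical counts.
#' @return data.frame: member columns plus `captured` molecule counts.
#' @export
simulate_capture <- function(truth, mode = NULL, seed = 1L) {
  stopifnot(inherits(truth, "del_truth"))
  f <- effective_folds(truth, mode)
  p <- truth$base_capture_prob * f
  if (any(p > 1)) {
    warning(sum(p > 1), " member(s) had capture probability > 1; capped at 1")
    p <- pmin(p, 1)
  }
  out <- truth$members
  out$captured <- withr::with_seed(seed,
    rbinom(length(p), size = truth$copies_per_member, prob = p))
  out
}

mutate_reads <- function(seqs, error_rate, alphabet = DNA_ALPHABET) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), L, error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(L, n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(alphabet, cur), 1L)
    }
  }
  seqs
}

#' Simulate high-throughput sequencing of a captured pool
#'
#' Aggregates captured molecule counts over stereoisomers (both isomers
#' share one code pair), draws exactly `depth` reads multinomially with
#' probabilities proportional to the per-pair totals, assembles each read as
#' `prefix + CodeA + spacer + CodeB + suffix`, applies i.i.d. per-base
#' substitution errors, and writes a phred-33 FASTQ (constant quality "I")
#' plus a truth table recording the source code pair of every read.
#'
#' @param captured data.frame from [simulate_capture()].
#' @param manifest the `del_manifest` supplying codebooks and read layout.
#' @param cfg a `del_seqcfg`.
#' @param fastq output FASTQ path.
#' @param truth_table output TSV path (default `<fastq>.truth.tsv`) with
#'   columns `read_id`, `code_a`, `code_b`.
#' @return invisible list with `fastq`, `truth_table`, and `true_counts`
#'   (a `del_counts` aggregation of the truth table).
#' @export
sequence_reads <- function(captured, manifest, cfg, fastq,
                           truth_table = paste0(fastq, ".truth.tsv")) {
  stopifnot(inherits(cfg, "del_seqcfg"))
  validate_manifest(manifest)
  agg <- aggregate_pairs(captured, manifest)
  if (cfg$depth > 0 && sum(agg$count) == 0)
    stop("cannot sequence: requested depth ", cfg$depth,
         " but no molecules were captured")
  ca <- manifest$codebook_a
  cb <- manifest$codebook_b
  n_a <- nrow(ca)
  ia <- match(agg$code_a, ca$code_id)
  ib <- match(agg$code_b, cb$code_id)
  withr::with_seed(cfg$seed, {
    per_pair <- if (cfg$depth > 0)
      as.vector(rmultinom(1L, cfg$depth, prob = agg$count))
    else integer(nrow(agg))
    src <- rep.int(seq_len(nrow(agg)), per_pair)
    if (length(src) > 1L) src <- sample(src)
    seqs <- paste0(manifest$layout$prefix, ca$sequence[ia[src]],
                   manifest$layout$spacer, cb$sequence[ib[src]],
                   manifest$layout$suffix)
    seqs <- mutate_reads(seqs, cfg$error_rate)
  })
  ids <- sprintf("read%07d", seq_along(src))
  write_fastq(ids, seqs, fastq)
  tt <- data.frame(read_id = ids, code_a = agg$code_a[src],
                   code_b = agg$code_b[src], stringsAsFactors = FALSE)
  write.table(tt, truth_table, sep = "\t", quote = FALSE, row.names = FALSE)
  true_counts <- matrix(
    tabulate((ib[src] - 1L) * n_a + ia[src], nbins = n_a * nrow(cb)),
    n_a, nrow(cb), dimnames = list(ca$code_id, cb$code_id))
  invisible(list(fastq = fastq, truth_table = truth_table,
                 true_counts = del_counts(true_counts)))
}

# sum captured molecules over stereoisomers onto the CodeA x CodeB grid,
# in codebook order
aggregate_pairs <- function(captured, manifest) {
  a_ids <- manifest$codebook_a$code_id
  b_ids <- manifest$codebook_b$code_id
  ia <- match(captured$code_a, a_ids)
  ib <- match(captured$code_b, b_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("captured table contains code ids absent from the manifest")
  idx <- (ib - 1L) * length(a_ids) + ia
  tot <- rowsum(as.numeric(captured$captured), idx)
  g <- expand.grid(code_a = a_ids, code_b = b_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$count <- 0
  g$count[as.integer(rownames(tot))] <- tot[, 1L]
  g
}

write_fastq <- function(ids, seqs, path) {
  if (length(seqs)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Read a simulator truth table back as a count matrix
#'
#' @param truth_table path to the TSV written by [sequence_reads()].
#' @param manifest the matching `del_manifest`.
#' @return a `del_counts` aggregation of the true per-pair read counts.
#' @export
truth_counts <- function(truth_table, manifest) {
  tt <- read.delim(truth_table, stringsAsFactors = FALSE)
  a_ids <- manifest$codebook_a$code_id
  b_ids <- manifest$codebook_b$code_id
  ia <- match(tt$code_a, a_ids)
  ib <- match(tt$code_b, b_ids)
  m <- matrix(tabulate((ib - 1L) * length(a_ids) + ia,
                       nbins = length(a_ids) * length(b_ids)),
              length(a_ids), length(b_ids),
              dimnames = list(a_ids, b_ids))
  del_counts(m)
}
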