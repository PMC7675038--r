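#' Count matrix of decoded reads
#'
#' Container for decoded selection output: an integer CodeA-by-CodeB grid
#' plus total sequence counts (TCs = sum of the grid), average sequence
#' counts (ACs = TCs / grid size), and per-reason discard tallies for reads
#' that could not be assigned.
#'
#' @param counts integer matrix, rows CodeA ids, columns CodeB ids.
#' @param discarded named integer vector with elements `no-match-A`,
#'   `no-match-B`, `ambiguous`.
#' @return object of class `del_counts` with fields `counts`, `tcs`, `acs`,
#'   `discarded`.
#' @export
del_counts <- function(counts,
                       discarded = c("no-match-A" = 0L, "no-match-B" = 0L,
                                     "ambiguous" = 0L)) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(rownames(counts)), !is.null(colnames(counts)))
  tcs <- sum(as.numeric(counts))
  structure(list(counts = counts, tcs = tcs,
                 acs = tcs / length(counts),
                 discarded = discarded),
            class = "del_counts")
}

#' @export
print.del_counts <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("DEL count fingerprint: %d x %d code grid\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  TCs = %s, ACs = %s\n",
              format(s$tcs, big.mark = ","), format(s$acs_display)))
  if (sum(x$discarded) > 0)
    cat(sprintf("  discarded: %s\n",
                paste(sprintf("%s=%d", names(x$discarded), x$discarded),
                      collapse = ", ")))
  invisible(x)
}

#' Summarise a decoded count matrix
#'
#' Reports TCs, ACs (full precision and the display value, rounded half-up
#' to two decimals with integer ACs shown unrounded) and discard fractions.
#'
#' @param object a `del_counts`.
#' @param ... unused.
#' @return list with `tcs`, `acs`, `acs_display`, `discarded`,
#'   `discard_fraction`, `n_reads`.
#' @export
summary.del_counts <- function(object, ...) {
  n_reads <- object$tcs + sum(object$discarded)
  list(tcs = object$tcs,
       acs = object$acs,
       acs_display = acs_display(object$tcs, length(object$counts)),
       discarded = object$discarded,
       discard_fraction = if (n_reads > 0)
         sum(object$discarded) / n_reads else 0,
       n_reads = n_reads)
}

#' Display value of the ACs statistic
#'
#' ACs = TCs / (number of CodeA x CodeB combinations), rounded half-up to
#' two decimals; integer-valued ACs are displayed unrounded (e.g. a
#' 17,046,900-read run over the 183,300-pair grid displays 93).
#'
#' @param tcs total sequence counts.
#' @param n_cells grid size |A| x |B|.
#' @return numeric display value.
#' @export
acs_display <- function(tcs, n_cells) {
  stopifnot(n_cells > 0)
  acs <- tcs / n_cells
  if (isTRUE(all.equal(acs, round(acs)))) round(acs)
  else round_half_up(acs, 2)
}

#' Error-tolerant barcode matching
#'
#' Matches observed code-slot sequences against a codebook, accepting the
#' unique code within Hamming distance `max_mismatch`. If two or more codes
#' tie at the minimum qualifying distance the observation is `ambiguous`;
#' if none qualifies it is `none`. `max_mismatch` must be strictly below
#' the codebook's design distance `d_min`, otherwise nearest-neighbour
#' correction is not guaranteed unique and the call is refused.
#'
#' @param observed character vector of observed sequences (code length).
#' @param codebook data.frame with `code_id`, `sequence` columns.
#' @param max_mismatch maximum Hamming distance accepted.
#' @param d_min the codebook's design distance (default 3); used only for
#'   the `max_mismatch < d_min` configuration check.
#' @return data.frame `(observed, code_id, status)` with `status` one of
#'   `assigned`, `none`, `ambiguous`; `code_id` is `NA` unless assigned.
#' @export
#' @examples
#' cb <- generate_codebook(4, length = 8, d_min = 3, seed = 1)
#' obs <- cb$sequence[1]
#' substr(obs, 2, 2) <- setdiff(c("A","C","G","T"), substr(obs, 2, 2))[1]
#' match_code(obs, cb, max_mismatch = 1)
match_code <- function(observed, codebook, max_mismatch = 1L, d_min = 3L) {
  if (max_mismatch >= d_min)
    stop("max_mismatch (", max_mismatch, ") must be < d_min (", d_min,
         "): correction is no longer unique in the worst case")
  L <- nchar(codebook$sequence[1])
  if (any(nchar(observed) != L))
    stop("observed sequences must have the code length ", L)
  res <- match_code_idx(observed, codebook$sequence, max_mismatch)
  data.frame(observed = observed,
             code_id = ifelse(is.na(res$idx), NA_character_,
                              codebook$code_id[res$idx]),
             status = res$status, stringsAsFactors = FALSE)
}

# vectorised matcher returning codebook row indices; exact matches via
# hash lookup, the rest via Hamming search over unique observations
match_code_idx <- function(observed, code_seqs, max_mismatch) {
  idx <- match(observed, code_seqs)
  status <- ifelse(is.na(idx), "none", "assigned")
  todo <- which(is.na(idx))
  if (length(todo) && max_mismatch >= 1L) {
    u <- unique(observed[todo])
    um <- seq_char_matrix(u)
    tcm <- t(seq_char_matrix(code_seqs))
    u_idx <- integer(length(u))
    u_status <- character(length(u))
    for (j in seq_along(u)) {
      d <- colSums(tcm != um[j, ])
      dmin <- min(d)
      if (dmin > max_mismatch) {
        u_idx[j] <- NA_integer_
        u_status[j] <- "none"
      } else if (sum(d == dmin) > 1L) {
        u_idx[j] <- NA_integer_
        u_status[j] <- "ambiguous"
      } else {
        u_idx[j] <- which.min(d)
        u_status[j] <- "assigned"
      }
    }
    k <- match(observed[todo], u)
    idx[todo] <- u_idx[k]
    status[todo] <- u_status[k]
  }
  list(idx = idx, status = status)
}

#' Decode a FASTQ file into a count fingerprint
#'
#' Parses fixed-layout reads (`prefix + CodeA + spacer + CodeB + suffix`),
#' matches both code slots with [match_code()] semantics, and aggregates
#' assigned reads on the CodeA-by-CodeB grid. Every read ends in exactly
#' one grid cell or one discard bin, so assigned + discarded equals reads
#' processed. Discard reasons: slot A is inspected first — an ambiguous
#' slot gives `ambiguous`, an unmatched slot A gives `no-match-A`,
#' otherwise slot B decides (`ambiguous` or `no-match-B`).
#'
#' @param fastq path to a phred-33 FASTQ file.
#' @param manifest the `del_manifest` describing codebooks and layout.
#' @param max_mismatch maximum Hamming distance per code slot (must be
#'   < the manifest's `d_min`).
#' @return a `del_counts`.
#' @export
decode_fastq <- function(fastq, manifest, max_mismatch = 1L) {
  validate_manifest(manifest)
  if (max_mismatch >= manifest$d_min)
    stop("max_mismatch (", max_mismatch, ") must be < d_min (",
         manifest$d_min, "): correction is no longer unique in the worst case")
  ca <- manifest$codebook_a
  cb <- manifest$codebook_b
  La <- nchar(ca$sequence[1])
  Lb <- nchar(cb$sequence[1])
  off_a <- nchar(manifest$layout$prefix) + 1L
  off_b <- off_a + La + nchar(manifest$layout$spacer)
  expected_len <- off_b + Lb + nchar(manifest$layout$suffix) - 1L
  empty <- del_counts(matrix(0L, nrow(ca), nrow(cb),
                             dimnames = list(ca$code_id, cb$code_id)))
  if (file.size(fastq) == 0) return(empty)
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  if (length(reads) == 0L) return(empty)
  bad <- which(nchar(reads) != expected_len)
  if (length(bad))
    stop("read ", bad[1], " has length ", nchar(reads[bad[1]]),
         ", expected ", expected_len, " for the configured layout")
  obs_a <- substr(reads, off_a, off_a + La - 1L)
  obs_b <- substr(reads, off_b, off_b + Lb - 1L)
  ra <- match_code_idx(obs_a, ca$sequence, max_mismatch)
  rb <- match_code_idx(obs_b, cb$sequence, max_mismatch)
  ok <- ra$status == "assigned" & rb$status == "assigned"
  reason <- ifelse(ra$status == "ambiguous", "ambiguous",
            ifelse(ra$status == "none", "no-match-A",
            ifelse(rb$status == "ambiguous", "ambiguous", "no-match-B")))
  disc <- table(factor(reason[!ok],
                       levels = c("no-match-A", "no-match-B", "ambiguous")))
  m <- matrix(tabulate((rb$idx[ok] - 1L) * nrow(ca) + ra$idx[ok],
                       nbins = nrow(ca) * nrow(cb)),
              nrow(ca), nrow(cb), dimnames = list(ca$code_id, cb$code_id))
  del_counts(m, discarded = setNames(as.integer(disc), names(disc)))
}

#' Write / read a count matrix as TSV
#'
#' The on-disk format is long-form `(code_a, code_b, count)` with zero
#' cells omitted; [read_counts()] restores the full grid from the manifest.
#'
#' @param x a `del_counts`.
#' @param path output TSV path.
#' @return `path` (write) or a `del_counts` (read), invisibly for write.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "del_counts"))
  nz <- which(x$counts > 0, arr.ind = TRUE)
  df <- data.frame(code_a = rownames(x$counts)[nz[, 1]],
                   code_b = colnames(x$counts)[nz[, 2]],
                   count = x$counts[nz])
  df <- df[order(df$code_a, df$code_b), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param manifest the `del_manifest` defining the grid.
#' @export
read_counts <- function(path, manifest) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  a_ids <- manifest$codebook_a$code_id
  b_ids <- manifest$codebook_b$code_id
  ia <- match(df$code_a, a_ids)
  ib <- match(df$code_b, b_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("count table contains code ids absent from the manifest")
  m <- matrix(0L, length(a_ids), length(b_ids),
              dimnames = list(a_ids, b_ids))
  m[cbind(ia, ib)] <- df$count
  del_counts(m)
}
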