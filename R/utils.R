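DNA_ALPHABET <- c("A", "C", "G", "T")

#' Round half up
#'
#' Decimal rounding with ties going away from zero, as used for displayed
#' average sequence counts (ACs). Base `round()` rounds half to even, which
#' disagrees with caption-style display values such as 1.87.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(1.875, 2) # 1.88, where round() gives 1.88 or 1.87
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# split equal-length sequences into an n x L character matrix
seq_char_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must share one length, got lengths: ",
         paste(sort(unique(nchar(seqs))), collapse = ", "))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}

# pairwise minimum Hamming distance, O(n^2 L); returns the minimum and the
# index pair achieving it
min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(list(min = Inf, pair = c(NA_integer_, NA_integer_)))
  m <- seq_char_matrix(seqs)
  tm <- t(m)
  best <- Inf
  pair <- c(NA_integer_, NA_integer_)
  for (i in seq_len(n - 1L)) {
    d <- colSums(tm[, (i + 1L):n, drop = FALSE] != m[i, ])
    j <- which.min(d)
    if (d[j] < best) {
      best <- d[j]
      pair <- c(i, i + j)
    }
    if (best == 0L) break
  }
  list(min = best, pair = pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., file = NULL) {
  txt <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  message(txt)
  if (!is.null(file)) cat(txt, "\n", file = file, append = TRUE, sep = "")
  invisible(txt)
}
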