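#' Enrichment factors for a decoded selection
#'
#' Computes per-combination enrichment factors (EF) from a count
#' fingerprint. Two baselines are supported:
#'
#' * `uniform` (default): `ef_i = c_i / (TCs / N)` with `N = |A| x |B|` —
#'   the fold over-representation relative to the flat expectation over the
#'   full grid. The grid mean of this EF is exactly 1, matching how the
#'   published ACs statistic normalises against all 183,300 combinations.
#' * `library`: `ef_i = (c_i / TCs) / ((c0_i + pi) / (TCs0 + pi * N))` —
#'   frequency relative to an unselected-library reference with pseudocount
#'   `pi` guarding unsampled reference cells.
#'
#' @param x a `del_counts` for the selection.
#' @param baseline `"uniform"` or `"library"`.
#' @param reference a `del_counts` of the unselected library (library
#'   baseline only).
#' @param pseudocount pseudocount for the library baseline (default 0.5).
#' @param target,mode,replicate optional selection metadata carried as
#'   attributes.
#' @return a `del_ef` data.frame `(code_a, code_b, count, ef)` over the
#'   full grid, with attributes `baseline`, `tcs`, `target`, `mode`,
#'   `replicate`.
#' @export
enrichment_factors <- function(x, baseline = c("uniform", "library"),
                               reference = NULL, pseudocount = 0.5,
                               target = NA_character_, mode = "SP",
                               replicate = 1L) {
  stopifnot(inherits(x, "del_counts"))
  baseline <- match.arg(baseline)
  if (x$tcs == 0) stop("cannot compute enrichment factors: TCs = 0")
  n <- length(x$counts)
  df <- data.frame(
    code_a = rep(rownames(x$counts), times = ncol(x$counts)),
    code_b = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts), stringsAsFactors = FALSE)
  if (baseline == "uniform") {
    df$ef <- df$count / (x$tcs / n)
  } else {
    if (is.null(reference) || !inherits(reference, "del_counts"))
      stop("library baseline requires an unselected-library reference ",
           "del_counts")
    if (!identical(dim(reference$counts), dim(x$counts)))
      stop("reference grid (", nrow(reference$counts), " x ",
           ncol(reference$counts), ") does not match selection grid")
    ref <- as.vector(reference$counts)
    df$ef <- (df$count / x$tcs) /
      ((ref + pseudocount) / (reference$tcs + pseudocount * n))
  }
  structure(df, class = c("del_ef", "data.frame"), baseline = baseline,
            tcs = x$tcs, target = target, mode = mode, replicate = replicate)
}

check_same_grid <- function(tables) {
  key <- function(t) paste(t$code_a, t$code_b, sep = "|")
  k1 <- key(tables[[1]])
  for (t in tables[-1])
    if (!identical(k1, key(t)))
      stop("enrichment tables are not over the same CodeA x CodeB grid")
  invisible(TRUE)
}

#' Rank and threshold enriched combinations
#'
#' Returns the combinations with `ef >= ef_min` and `count >= count_min`,
#' sorted by EF descending with a stable (code_a, code_b) lexicographic
#' tie-break.
#'
#' @param table a `del_ef`.
#' @param ef_min minimum enrichment factor (default 10).
#' @param count_min minimum raw count (default 3).
#' @return data.frame of hits with a `rank` column.
#' @export
call_hits <- function(table, ef_min = 10, count_min = 3) {
  stopifnot(inherits(table, "del_ef"), ef_min >= 0, count_min >= 0)
  hits <- table[table$ef >= ef_min & table$count >= count_min, , drop = FALSE]
  o <- order(-hits$ef, hits$code_a, hits$code_b)
  hits <- as.data.frame(hits)[o, , drop = FALSE]
  rownames(hits) <- NULL
  if (nrow(hits)) hits$rank <- seq_len(nrow(hits))
  else hits$rank <- integer(0)
  hits
}

#' Consensus hits across selection replicates
#'
#' Selections are typically run in triplicate; a combination is a consensus
#' hit only if it passes the EF and count thresholds in *every* replicate.
#' Reported per combination: minimum and median EF across replicates.
#'
#' @param tables list of >= 2 `del_ef` tables over the same grid.
#' @param ef_min,count_min thresholds as in [call_hits()].
#' @return data.frame `(code_a, code_b, n_replicates, ef_min_rep,
#'   ef_median)` sorted by minimum EF descending.
#' @export
replicate_concordance <- function(tables, ef_min = 10, count_min = 3) {
  if (length(tables) < 2L)
    stop("replicate concordance needs >= 2 enrichment tables")
  stopifnot(all(vapply(tables, inherits, logical(1), "del_ef")))
  check_same_grid(tables)
  pass <- Reduce(`&`, lapply(tables, function(t)
    t$ef >= ef_min & t$count >= count_min))
  efs <- do.call(cbind, lapply(tables, `[[`, "ef"))
  out <- data.frame(code_a = tables[[1]]$code_a[pass],
                    code_b = tables[[1]]$code_b[pass],
                    n_replicates = rep(length(tables), sum(pass)),
                    ef_min_rep = apply(efs[pass, , drop = FALSE], 1, min),
                    ef_median = apply(efs[pass, , drop = FALSE], 1, median),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ef_min_rep, out$code_a, out$code_b), ]
  rownames(out) <- NULL
  out
}

#' Single- vs dual-pharmacophore synergy analysis
#'
#' Compares enrichment of every combination between the plain library
#' selection (SP) and the "2+1" selection in which the library is annealed
#' to a complementary strand displaying a known hit moiety (DP). The
#' synergy ratio is `ef_dp / max(ef_sp, 1)` — the denominator floor
#' prevents ratio inflation from sub-background SP values. Combinations are
#' classified, mutually exclusively, as:
#'
#' * `synergistic` — ratio >= `ratio_min` and `ef_dp >= ef_dp_min`: the
#'   building blocks potentiate the displayed hit (affinity-maturation
#'   candidates);
#' * `independent` — both `ef_sp` and `ef_dp` >= `ef_dp_min` with ratio <
#'   `ratio_min`: a binder in its own right, unaffected by the hit;
#' * `sp-only` — `ef_sp >= ef_dp_min` but `ef_dp < ef_dp_min`: enrichment
#'   lost upon hybridisation;
#' * `background` — everything else.
#'
#' @param sp,dp `del_ef` tables over the same grid for the same target.
#' @param ratio_min minimum synergy ratio (default 5).
#' @param ef_dp_min minimum DP enrichment factor (default 10).
#' @param hit_label label of the displayed moiety, carried into the report.
#' @return a `del_synergy` data.frame `(code_a, code_b, count_sp, count_dp,
#'   ef_sp, ef_dp, synergy_ratio, classification)`.
#' @export
#' @examples
#' # the published exemplar EF pairs: SP 3 -> DP 22 and SP 3 -> DP 1119
#' # both classify as synergistic under the default thresholds
synergy_analysis <- function(sp, dp, ratio_min = 5, ef_dp_min = 10,
                             hit_label = attr(dp, "target")) {
  stopifnot(inherits(sp, "del_ef"), inherits(dp, "del_ef"))
  check_same_grid(list(sp, dp))
  out <- data.frame(code_a = sp$code_a, code_b = sp$code_b,
                    count_sp = sp$count, count_dp = dp$count,
                    ef_sp = sp$ef, ef_dp = dp$ef, stringsAsFactors = FALSE)
  out$synergy_ratio <- out$ef_dp / pmax(out$ef_sp, 1)
  out$classification <- classify_synergy(out$ef_sp, out$ef_dp,
                                         out$synergy_ratio,
                                         ratio_min, ef_dp_min)
  structure(out, class = c("del_synergy", "data.frame"),
            ratio_min = ratio_min, ef_dp_min = ef_dp_min,
            hit_label = hit_label)
}

classify_synergy <- function(ef_sp, ef_dp, ratio, ratio_min, ef_dp_min) {
  ifelse(ratio >= ratio_min & ef_dp >= ef_dp_min, "synergistic",
  ifelse(ef_sp >= ef_dp_min & ef_dp >= ef_dp_min, "independent",
  ifelse(ef_sp >= ef_dp_min, "sp-only", "background")))
}
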