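#' Named simulation scenarios
#'
#' Parameter bundles reproducing the published selection campaigns at their
#' printed sequencing depths:
#'
#' * `"unselected"` — naive library sequencing, all folds 1, depth
#'   17,046,900 reads (ACs 93 over the 183,300-pair grid).
#' * `"sp_selection"` — single-pharmacophore streptavidin/CAIX-style
#'   selection at depth 232,900: one planted binder on the aromatic
#'   sulfonamide control pair A94/B575 at fold 1000 (both stereoisomers),
#'   giving a closed-form expected enrichment factor near 10^3, the scale
#'   of the strongest published sulfonamide enrichments.
#' * `"dp_maturation"` — dual-pharmacophore affinity maturation in the
#'   serum-albumin style: a synergistic pair A24/B137 (SP fold 3, DP
#'   synergy multiplier 373, so effective DP fold 1119) and an independent
#'   strong binder A200/B244 (fold 112 in both modes); SP depth 190,200,
#'   DP depth 241,800.
#' * `"triplicate"` — the sp_selection truth with three sequencing
#'   configurations at seeds seed, seed+1, seed+2.
#'
#' All scenarios use base capture probability 1e-5, 1e7 copies per member,
#' and substitution error rate 0.005.
#'
#' @param name scenario name.
#' @param manifest a `del_manifest` (defaults to the full-scale design;
#'   pass a smaller manifest for quick runs — planted pairs are then placed
#'   on the last A/B codes of the grid).
#' @param seed integer seed propagated to capture and sequencing.
#' @param depth optional depth override (reads).
#' @return list with elements `truth` (`del_truth`), `mode_sp` and, for DP
#'   scenarios, `mode_dp` (`del_mode`), `cfg` (one `del_seqcfg`, or a list
#'   of three for `"triplicate"`, or `cfg_sp`/`cfg_dp` for
#'   `"dp_maturation"`), and `planted` (data.frame of planted pairs).
#' @export
scenario_preset <- function(name = c("unselected", "sp_selection",
                                     "dp_maturation", "triplicate"),
                            manifest = gbdel_manifest(),
                            seed = 1L, depth = NULL) {
  name <- match.arg(name)
  truth <- ground_truth(manifest)
  err <- 0.005
  # map the published exemplar codes onto the manifest, falling back to the
  # top-right corner of smaller grids
  pick <- function(id, ids) if (id %in% ids) id else ids[length(ids)]
  pick2 <- function(id, ids) {
    if (id %in% ids) id else ids[max(1L, length(ids) - 1L)]
  }
  a_ids <- manifest$blocks_a$block_id
  b_ids <- manifest$blocks_b$block_id
  switch(name,
    unselected = list(
      truth = truth,
      mode_sp = selection_mode("SP"),
      cfg = sequencing_config(depth %||% 17046900, err, seed),
      planted = data.frame(code_a = character(), code_b = character(),
                           fold = numeric())),
    sp_selection = {
      pa <- pick("A94", a_ids)
      pb <- pick("B575", b_ids)
      truth <- plant_binder(truth, pa, pb, fold = 1000)
      list(truth = truth, mode_sp = selection_mode("SP"),
           cfg = sequencing_config(depth %||% 232900, err, seed),
           planted = data.frame(code_a = pa, code_b = pb, fold = 1000))
    },
    dp_maturation = {
      sa <- pick("A24", a_ids)
      sb <- pick("B137", b_ids)
      ia_ <- pick2("A200", a_ids)
      ib_ <- pick2("B244", b_ids)
      truth <- plant_binder(truth, sa, sb, fold = 3)
      truth <- plant_binder(truth, ia_, ib_, fold = 112)
      mult <- data.frame(a_id = sa, b_id = sb, multiplier = 373)
      list(truth = truth,
           mode_sp = selection_mode("SP"),
           mode_dp = selection_mode("DP", hit_label = "HIT2",
                                    multipliers = mult),
           cfg_sp = sequencing_config(depth %||% 190200, err, seed),
           cfg_dp = sequencing_config(depth %||% 241800, err, seed + 10L),
           planted = data.frame(
             code_a = c(sa, ia_), code_b = c(sb, ib_),
             fold = c(3, 112), dp_multiplier = c(373, 1),
             class = c("synergistic", "independent")))
    },
    triplicate = {
      base <- scenario_preset("sp_selection", manifest, seed, depth)
      base$cfg <- lapply(0:2, function(k)
        sequencing_config(base$cfg$depth, err, seed + k))
      base
    })
}

#' Closed-form expected enrichment factors for a simulated selection
#'
#' Under the binomial-capture / multinomial-sequencing model, the expected
#' decoded count of pair i is depth * w_i / sum(w), with capture weights
#' w_i = copies * sum over stereoisomers of min(1, p0 * fold_eff). The
#' expected uniform-baseline enrichment factor is therefore N * w_i /
#' sum(w). This is the analytic oracle used to check simulated EFs.
#'
#' @param truth a `del_truth`.
#' @param mode optional `del_mode`.
#' @param manifest the matching `del_manifest`.
#' @return data.frame `(code_a, code_b, weight, expected_ef)` over the grid.
#' @export
expected_ef <- function(truth, manifest, mode = NULL) {
  f <- effective_folds(truth, mode)
  w_member <- pmin(1, truth$base_capture_prob * f)
  cap <- truth$members
  cap$captured <- w_member # weights, not draws
  agg <- aggregate_pairs(cap, manifest)
  n <- nrow(agg)
  agg$weight <- agg$count
  agg$expected_ef <- n * agg$weight / sum(agg$weight)
  agg[, c("code_a", "code_b", "weight", "expected_ef")]
}
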