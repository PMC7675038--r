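random_counts <- function(n_a, n_b, seed, lambda = 3) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_a * n_b, lambda), n_a, n_b,
                dimnames = list(paste0("A", seq_len(n_a)),
                                paste0("B", seq_len(n_b))))
  })
  del_counts(m)
}

test_that("uniform-baseline EF has grid mean 1 and is scale invariant", {
  for (seed in 1:10) {
    x <- random_counts(12, 17, seed)
    ef <- enrichment_factors(x)
    expect_lt(abs(mean(ef$ef) - 1), 1e-12)
    # multiplying all counts by k leaves EF unchanged
    ef5 <- enrichment_factors(del_counts(x$counts * 5L))
    expect_equal(ef5$ef, ef$ef)
  }
})

test_that("a single occupied cell carries EF = N, the rest 0", {
  m <- matrix(0L, 4, 6, dimnames = list(paste0("A", 1:4), paste0("B", 1:6)))
  m[2, 3] <- 777L
  ef <- enrichment_factors(del_counts(m))
  expect_equal(sort(unique(ef$ef)), c(0, 24))
  expect_equal(ef$ef[ef$code_a == "A2" & ef$code_b == "B3"], 24)
})

test_that("library-baseline EF matches an independent recomputation", {
  x <- random_counts(8, 9, seed = 4)
  ref <- random_counts(8, 9, seed = 5, lambda = 10)
  ef <- enrichment_factors(x, baseline = "library", reference = ref,
                           pseudocount = 0.5)
  n <- 72
  manual <- (as.vector(x$counts) / x$tcs) /
    ((as.vector(ref$counts) + 0.5) / (ref$tcs + 0.5 * n))
  expect_equal(ef$ef, manual)
  expect_error(enrichment_factors(x, baseline = "library"), "reference")
})

test_that("EF computation rejects empty selections", {
  m <- matrix(0L, 2, 2, dimnames = list(c("A1", "A2"), c("B1", "B2")))
  expect_error(enrichment_factors(del_counts(m)), "TCs = 0")
})

test_that("hit calling thresholds, ranks, and breaks ties lexicographically", {
  m <- matrix(1L, 3, 3, dimnames = list(paste0("A", 1:3), paste0("B", 1:3)))
  m[1, 2] <- 50L
  m[3, 1] <- 50L
  m[2, 2] <- 20L
  ef <- enrichment_factors(del_counts(m))
  hits <- call_hits(ef, ef_min = 1, count_min = 3) # EFs: 3.57, 3.57, 1.43
  expect_identical(nrow(hits), 3L)
  # two EF ties rank by (code_a, code_b)
  expect_identical(hits$code_a, c("A1", "A3", "A2"))
  expect_identical(hits$rank, 1:3)

  all_cells <- call_hits(ef, ef_min = 0, count_min = 0)
  expect_identical(nrow(all_cells), 9L)
  expect_identical(all_cells$rank, 1:9)
})

test_that("hit calling under a background-only selection is near-empty", {
  m <- toy_manifest(n_a = 15, n_b = 20)
  run <- toy_selection(m, "A1", "B1", fold = 1, depth = 400, seed = 3)
  # ACs ~ 1.3, no planted signal: EF >= 10 with count >= 3 demands a cell
  # with >= 10x the mean, essentially impossible at Poisson(1.3)
  hits <- call_hits(enrichment_factors(run$decoded), ef_min = 10,
                    count_min = 3)
  expect_lte(nrow(hits), 1L)
})

test_that("a planted binder tops the ranking and survives triplicates", {
  m <- toy_manifest(n_a = 10, n_b = 12)
  tables <- lapply(1:3, function(s) {
    run <- toy_selection(m, "A4", "B7", fold = 500, depth = 6000, seed = s)
    enrichment_factors(run$decoded)
  })
  for (t in tables) {
    hits <- call_hits(t)
    expect_identical(hits$code_a[1], "A4")
    expect_identical(hits$code_b[1], "B7")
  }
  cons <- replicate_concordance(tables, ef_min = 10, count_min = 3)
  expect_true(any(cons$code_a == "A4" & cons$code_b == "B7"))
  # min/median EF are consistent with the member tables
  efs <- vapply(tables, function(t)
    t$ef[t$code_a == "A4" & t$code_b == "B7"], numeric(1))
  i <- which(cons$code_a == "A4" & cons$code_b == "B7")
  expect_equal(cons$ef_min_rep[i], min(efs))
  expect_equal(cons$ef_median[i], median(efs))
})

test_that("replicate concordance needs >= 2 tables on one grid", {
  x <- enrichment_factors(random_counts(4, 4, 1))
  expect_error(replicate_concordance(list(x)), ">= 2")
  y <- enrichment_factors(random_counts(5, 4, 2))
  expect_error(replicate_concordance(list(x, y)), "same CodeA x CodeB grid")
})

test_that("disjoint spurious hits across replicates yield an empty consensus", {
  mk <- function(hot_cell, seed) {
    m <- matrix(1L, 6, 6, dimnames = list(paste0("A", 1:6), paste0("B", 1:6)))
    m[hot_cell[1], hot_cell[2]] <- 100L
    enrichment_factors(del_counts(m))
  }
  cons <- replicate_concordance(list(mk(c(1, 1)), mk(c(2, 5)), mk(c(6, 3))),
                                ef_min = 10, count_min = 3)
  expect_identical(nrow(cons), 0L)
})

synthetic_ef_pair <- function(ef_sp, ef_dp) {
  # two-cell grid carrying the exemplar EF values in cell 1
  mk <- function(ef) {
    df <- data.frame(code_a = c("A1", "A1"), code_b = c("B1", "B2"),
                     count = c(10L, 1L), ef = c(ef, 0.1))
    structure(df, class = c("del_ef", "data.frame"), baseline = "uniform",
              tcs = 11, target = "T", mode = "SP", replicate = 1L)
  }
  list(sp = mk(ef_sp), dp = mk(ef_dp))
}

test_that("published SP/DP exemplar enrichments classify as narrated", {
  # EF 3 -> 22 and 3 -> 1119: synergistic; flat background stays background;
  # a strong binder unchanged by the displayed hit is independent
  cases <- list(
    list(sp = 3, dp = 22, class = "synergistic", ratio = 22 / 3),
    list(sp = 3, dp = 1119, class = "synergistic", ratio = 373),
    list(sp = 1, dp = 1, class = "background", ratio = 1),
    list(sp = 112, dp = 112, class = "independent", ratio = 1))
  for (cs in cases) {
    p <- synthetic_ef_pair(cs$sp, cs$dp)
    rep <- synergy_analysis(p$sp, p$dp)
    expect_identical(rep$classification[1], cs$class)
    expect_equal(rep$synergy_ratio[1], cs$ratio)
  }
})

test_that("synergy handles the denominator floor and sp-only loss", {
  p <- synthetic_ef_pair(0.4, 20) # sub-background SP: ratio floored at ef_dp
  rep <- synergy_analysis(p$sp, p$dp)
  expect_equal(rep$synergy_ratio[1], 20)
  expect_identical(rep$classification[1], "synergistic")

  p <- synthetic_ef_pair(50, 2) # enrichment lost upon hybridisation
  expect_identical(synergy_analysis(p$sp, p$dp)$classification[1], "sp-only")
})

test_that("synergy classifications are exhaustive and mutually exclusive", {
  withr::with_seed(8, {
    ef_sp <- stats::runif(500, 0, 40)
    ef_dp <- stats::runif(500, 0, 40)
  })
  ratio <- ef_dp / pmax(ef_sp, 1)
  cls <- deldeck:::classify_synergy(ef_sp, ef_dp, ratio, 5, 10)
  expect_true(all(cls %in% c("synergistic", "independent", "sp-only",
                             "background")))
  # re-derive each class independently and compare
  syn <- ratio >= 5 & ef_dp >= 10
  ind <- !syn & ef_sp >= 10 & ef_dp >= 10
  spo <- !syn & !ind & ef_sp >= 10 & ef_dp < 10
  bg <- !(syn | ind | spo)
  expect_identical(cls == "synergistic", syn)
  expect_identical(cls == "independent", ind)
  expect_identical(cls == "sp-only", spo)
  expect_identical(cls == "background", bg)
  expect_error(synergy_analysis(synthetic_ef_pair(1, 1)$sp,
                                enrichment_factors(random_counts(3, 3, 1))),
               "grid")
})

test_that("simulated dual-pharmacophore maturation recovers planted classes", {
  # 600-pair grid: closed-form expected EFs are ~367 (DP, synergistic pair),
  # ~37 vs ~94 (DP vs SP, independent pair) — all far from the thresholds
  m <- toy_manifest(n_a = 20, n_b = 30)
  sc <- scenario_preset("dp_maturation", manifest = m, seed = 11,
                        depth = 12000)
  run_mode <- function(mode, cfg, seed) {
    cap <- simulate_capture(sc$truth, mode, seed = seed)
    fq <- tempfile(fileext = ".fastq")
    on.exit(unlink(c(fq, paste0(fq, ".truth.tsv"))))
    sequence_reads(cap, m, cfg, fq)
    enrichment_factors(decode_fastq(fq, m, max_mismatch = 1))
  }
  sp <- run_mode(sc$mode_sp, sc$cfg_sp, 11)
  dp <- run_mode(sc$mode_dp, sc$cfg_dp, 12)
  rep <- synergy_analysis(sp, dp)
  key <- paste(rep$code_a, rep$code_b)
  planted_key <- paste(sc$planted$code_a, sc$planted$code_b)
  expect_identical(rep$classification[key == planted_key[1]], "synergistic")
  expect_identical(rep$classification[key == planted_key[2]], "independent")
  # everything unplanted stays out of the synergistic class
  expect_identical(sum(rep$classification == "synergistic"), 1L)
})
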