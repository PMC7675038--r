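test_that("background capture counts match the n0 * p0 expectation", {
  m <- toy_manifest(n_a = 6, n_b = 8)
  truth <- ground_truth(m) # p0 = 1e-5, n0 = 1e7 -> expected 100 per member
  cap <- simulate_capture(truth, seed = 1)
  expect_identical(nrow(cap), 96L)
  # mean over 96 members: sd of the mean is 10/sqrt(96) ~ 1
  expect_lt(abs(mean(cap$captured) - 100), 5)
})

test_that("a planted fold-1000 binder is captured ~1000x over background", {
  m <- toy_manifest(n_a = 6, n_b = 8)
  truth <- plant_binder(ground_truth(m), "A2", "B3", fold = 1000)
  cap <- simulate_capture(truth, seed = 2)
  planted <- cap$captured[cap$a_id == "A2" & cap$b_id == "B3"]
  # Binomial(1e7, 1e-2): mean 1e5, sd ~ 315; check each stereoisomer at 5 sigma
  expect_length(planted, 2L)
  expect_true(all(abs(planted - 1e5) < 5 * sqrt(1e7 * 0.01 * 0.99)))
})

test_that("capture is reproducible under a fixed seed and caps p at 1", {
  m <- toy_manifest(n_a = 3, n_b = 3)
  truth <- plant_binder(ground_truth(m), "A1", "B1", fold = 1e7)
  expect_warning(cap1 <- simulate_capture(truth, seed = 5), "capped")
  cap2 <- suppressWarnings(simulate_capture(truth, seed = 5))
  cap3 <- suppressWarnings(simulate_capture(truth, seed = 6))
  expect_identical(cap1$captured, cap2$captured)
  expect_false(identical(cap1$captured, cap3$captured))
  # capped member is captured deterministically: all 1e7 copies
  expect_identical(cap1$captured[cap1$a_id == "A1" & cap1$b_id == "B1"],
                   c(1e7L, 1e7L))
})

test_that("raising a member's fold never decreases its expected decoded count", {
  m <- toy_manifest(n_a = 4, n_b = 4)
  mean_captured <- function(fold) {
    vals <- vapply(1:6, function(s) {
      truth <- plant_binder(ground_truth(m), "A3", "B2", fold = fold)
      cap <- simulate_capture(truth, seed = s)
      sum(cap$captured[cap$a_id == "A3" & cap$b_id == "B2"])
    }, numeric(1))
    mean(vals)
  }
  expect_true(mean_captured(2) < mean_captured(8))
  expect_true(mean_captured(8) < mean_captured(50))
})

test_that("sequencing emits exactly depth reads with a matching truth table", {
  m <- toy_manifest(n_a = 4, n_b = 5)
  cap <- simulate_capture(ground_truth(m), seed = 1)
  fq <- withr::local_tempfile(fileext = ".fastq")
  res <- sequence_reads(cap, m, sequencing_config(1000, error_rate = 0,
                                                  seed = 1), fq)
  tt <- read.delim(res$truth_table)
  expect_identical(nrow(tt), 1000L)
  expect_identical(res$true_counts$tcs, 1000)
  # zero-error reads: every code slot is byte-identical to its codebook entry
  reads <- unname(as.character(Biostrings::readDNAStringSet(fq,
                                                            format = "fastq")))
  obs_a <- substr(reads, 7, 14)  # layout: 6 prefix + 8 CodeA
  obs_b <- substr(reads, 19, 26) # + 4 spacer + 8 CodeB
  expect_identical(obs_a,
                   m$codebook_a$sequence[match(tt$code_a,
                                               m$codebook_a$code_id)])
  expect_identical(obs_b,
                   m$codebook_b$sequence[match(tt$code_b,
                                               m$codebook_b$code_id)])
})

test_that("uniform sequencing at depth = grid size has Poisson-like moments", {
  m <- toy_manifest(n_a = 20, n_b = 25)
  truth <- ground_truth(m)
  cap <- truth$members
  cap$captured <- 1000L # exactly uniform weights
  fq <- withr::local_tempfile(fileext = ".fastq")
  res <- sequence_reads(cap, m, sequencing_config(500, 0, seed = 3), fq)
  counts <- as.vector(res$true_counts$counts)
  expect_identical(length(counts), 500L)
  expect_equal(mean(counts), 1) # exact: depth / cells
  expect_lt(abs(var(counts) - 1), 0.35) # multinomial ~ Poisson(1)
})

test_that("substitution errors hit code slots at the closed-form rate", {
  m <- toy_manifest(n_a = 5, n_b = 5)
  cap <- simulate_capture(ground_truth(m), seed = 1)
  fq <- withr::local_tempfile(fileext = ".fastq")
  depth <- 20000L
  res <- sequence_reads(cap, m, sequencing_config(depth, 0.01, seed = 4), fq)
  tt <- read.delim(res$truth_table)
  reads <- unname(as.character(Biostrings::readDNAStringSet(fq,
                                                            format = "fastq")))
  obs_a <- substr(reads, 7, 14)
  true_a <- m$codebook_a$sequence[match(tt$code_a, m$codebook_a$code_id)]
  frac_err <- mean(obs_a != true_a)
  p <- 1 - 0.99^8 # expected fraction of reads with >= 1 error in the slot
  expect_lt(abs(frac_err - p), 4 * sqrt(p * (1 - p) / depth))
})

test_that("sequencing refuses depth > 0 with an all-zero capture", {
  m <- toy_manifest(n_a = 2, n_b = 2)
  cap <- ground_truth(m)$members
  cap$captured <- 0L
  expect_error(
    sequence_reads(cap, m, sequencing_config(10, 0, 1),
                   withr::local_tempfile(fileext = ".fastq")),
    "no molecules")
})

test_that("scenario presets encode the published campaign parameters", {
  m <- toy_manifest(n_a = 6, n_b = 8)
  un <- scenario_preset("unselected", manifest = m, seed = 1)
  expect_identical(un$cfg$depth, 17046900L)
  expect_true(all(un$truth$members$fold == 1))

  sp <- scenario_preset("sp_selection", manifest = m, seed = 1)
  expect_identical(sp$cfg$depth, 232900L)
  expect_identical(sort(unique(sp$truth$members$fold)), c(1, 1000))

  tri <- scenario_preset("triplicate", manifest = m, seed = 5)
  expect_length(tri$cfg, 3L)
  expect_identical(vapply(tri$cfg, `[[`, integer(1), "seed"), 5:7)

  dp <- scenario_preset("dp_maturation", manifest = m, seed = 1)
  expect_identical(dp$mode_dp$mode, "DP")
  expect_identical(dp$mode_dp$hit_label, "HIT2")
  expect_identical(dp$cfg_sp$depth, 190200L)
  expect_identical(dp$cfg_dp$depth, 241800L)
  # DP effective fold of the synergistic pair = 3 * 373 = 1119
  f <- deldeck:::effective_folds(dp$truth, dp$mode_dp)
  key <- paste(dp$truth$members$a_id, dp$truth$members$b_id)
  syn <- paste(dp$planted$code_a[1], dp$planted$code_b[1])
  expect_identical(unique(f[key == syn]), 1119)

  expect_error(scenario_preset("nonsense", manifest = m), "arg")
})

test_that("DP mode requires a hit label and multipliers >= 1", {
  expect_error(selection_mode("DP"), "hit_label")
  expect_error(selection_mode("DP", "HIT1",
                              data.frame(a_id = "A1", b_id = "B1",
                                         multiplier = 0.5)),
               ">= 1")
})
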