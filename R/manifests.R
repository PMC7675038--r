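#' The full-scale two-code library manifest
#'
#' Builds the glutamic-acid scaffold library design at its published
#' composition: 300 building blocks A (191 primary amines, 36 secondary
#' amines, 72 heteroaromatic amines, plus one code reserved for an ammonia
#' control) and 611 building blocks B (480 carboxylic acids coupled as
#' amides, 131 alkynes coupled as triazoles), two stereoisomers per pair,
#' for 2 x 300 x 611 = 366,600 encoded compounds over 183,300 code pairs.
#' Barcode sequences are generated in-package (8 nt, minimum pairwise
#' Hamming distance 3) since no oligo sequences are published.
#'
#' With `with_properties = TRUE`, synthetic per-block mass/HBD/HBA/logP
#' contributions are drawn (seeded) so that the molecular-weight
#' distribution centres near 480 g/mol and most members satisfy the rule of
#' five, emulating the drug-like character of the real library; these
#' properties are synthetic stand-ins, not the unpublished real structures.
#'
#' @param seed integer seed driving codebook search and property draws.
#' @param with_properties attach synthetic property contributions?
#' @return a validated `del_manifest`.
#' @export
#' @examples
#' \donttest{
#' m <- gbdel_manifest(seed = 1)
#' nrow(m$blocks_a) * nrow(m$blocks_b) # 183300 code pairs
#' }
gbdel_manifest <- function(seed = 1L, with_properties = TRUE) {
  n_a <- 300L
  n_b <- 611L
  blocks_a <- data.frame(
    block_id = paste0("A", seq_len(n_a)),
    chem_class = c(rep("primary-amine", 191L), rep("secondary-amine", 36L),
                   rep("heteroaromatic-amine", 72L), "ammonia-control"),
    stringsAsFactors = FALSE)
  blocks_b <- data.frame(
    block_id = paste0("B", seq_len(n_b)),
    chem_class = c(rep("carboxylic-acid", 480L), rep("alkyne", 131L)),
    stringsAsFactors = FALSE)
  if (with_properties) {
    withr::with_seed(seed + 2L, {
      blocks_a$mass <- c(round(pmax(31, stats::rnorm(n_a - 1L, 120, 35)), 2),
                         17.03) # ammonia
      blocks_a$hbd <- c(sample(0:2, n_a - 1L, TRUE, prob = c(.5, .35, .15)), 2L)
      blocks_a$hba <- c(sample(0:3, n_a - 1L, TRUE), 1L)
      blocks_a$logp_contrib <- c(round(stats::rnorm(n_a - 1L, 0.9, 0.9), 2),
                                 -1.2)
      blocks_b$mass <- round(pmax(40, stats::rnorm(n_b, 165, 45)), 2)
      blocks_b$hbd <- sample(0:2, n_b, TRUE, prob = c(.55, .3, .15))
      blocks_b$hba <- sample(0:4, n_b, TRUE)
      blocks_b$logp_contrib <- round(stats::rnorm(n_b, 1.0, 1.0), 2)
    })
  }
  del_manifest(
    blocks_a = blocks_a, blocks_b = blocks_b,
    codebook_a = generate_codebook(n_a, length = 8L, d_min = 3L,
                                   seed = seed, role = "CodeA"),
    codebook_b = generate_codebook(n_b, length = 8L, d_min = 3L,
                                   seed = seed + 1L, role = "CodeB"),
    scaffold_mass = if (with_properties) 212.2 else NULL)
}

#' Small manifest for examples and tests
#'
#' A reduced design with the same structure as the full library: `n_a`
#' A-blocks (last one the ammonia control), `n_b` B-blocks (the last quarter
#' alkynes), two stereoisomers, in-package codebooks.
#'
#' @param n_a,n_b building-block counts per set.
#' @param stereo_labels stereoisomer labels.
#' @param code_length,d_min codebook geometry.
#' @param seed integer seed.
#' @param with_properties attach synthetic property contributions?
#' @return a validated `del_manifest`.
#' @export
toy_manifest <- function(n_a = 6L, n_b = 8L, stereo_labels = c("R", "S"),
                         code_length = 8L, d_min = 3L, seed = 1L,
                         with_properties = FALSE) {
  a_classes <- if (n_a >= 2L)
    c(rep("primary-amine", n_a - 1L), "ammonia-control")
  else rep("primary-amine", n_a)
  n_alk <- n_b %/% 4L
  b_classes <- c(rep("carboxylic-acid", n_b - n_alk), rep("alkyne", n_alk))
  blocks_a <- data.frame(block_id = paste0("A", seq_len(n_a)),
                         chem_class = a_classes, stringsAsFactors = FALSE)
  blocks_b <- data.frame(block_id = paste0("B", seq_len(n_b)),
                         chem_class = b_classes, stringsAsFactors = FALSE)
  if (with_properties) {
    withr::with_seed(seed + 2L, {
      blocks_a$mass <- round(pmax(31, stats::rnorm(n_a, 120, 35)), 2)
      blocks_a$hbd <- sample(0:2, n_a, TRUE)
      blocks_a$hba <- sample(0:3, n_a, TRUE)
      blocks_a$logp_contrib <- round(stats::rnorm(n_a, 0.9, 0.9), 2)
      blocks_b$mass <- round(pmax(40, stats::rnorm(n_b, 165, 45)), 2)
      blocks_b$hbd <- sample(0:2, n_b, TRUE)
      blocks_b$hba <- sample(0:4, n_b, TRUE)
      blocks_b$logp_contrib <- round(stats::rnorm(n_b, 1.0, 1.0), 2)
    })
  }
  del_manifest(
    blocks_a = blocks_a, blocks_b = blocks_b,
    codebook_a = generate_codebook(n_a, code_length, d_min, seed, "CodeA"),
    codebook_b = generate_codebook(n_b, code_length, d_min, seed + 1L,
                                   "CodeB"),
    stereo_labels = stereo_labels,
    scaffold_mass = if (with_properties) 212.2 else NULL,
    d_min = d_min)
}

#' Write a design manifest to a directory
#'
#' Serialises a manifest as sibling delimited-text files:
#' `blocks_a.tsv`, `blocks_b.tsv`, `codebook_a.tsv`, `codebook_b.tsv` and a
#' `design.yaml` holding stereo labels, scaffold properties, linkage deltas,
#' code geometry and read layout.
#'
#' @param manifest a validated `del_manifest`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  validate_manifest(manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wr(manifest$blocks_a, "blocks_a.tsv")
  wr(manifest$blocks_b, "blocks_b.tsv")
  wr(manifest$codebook_a, "codebook_a.tsv")
  wr(manifest$codebook_b, "codebook_b.tsv")
  yaml::write_yaml(list(
    stereo_labels = manifest$stereo_labels,
    scaffold_mass = manifest$scaffold_mass,
    linkage_deltas = manifest$linkage_deltas,
    scaffold_hbd = manifest$scaffold_hbd,
    scaffold_hba = manifest$scaffold_hba,
    scaffold_logp = manifest$scaffold_logp,
    code_length = nchar(manifest$codebook_a$sequence[1]),
    d_min = manifest$d_min,
    layout = manifest$layout), file.path(dir, "design.yaml"))
  invisible(dir)
}

#' Load and validate a design manifest from a directory
#'
#' Reads the sibling-file manifest format written by [write_manifest()] and
#' runs full validation; block counts are reported via `message()`.
#'
#' @param dir directory containing `blocks_a.tsv`, `blocks_b.tsv`,
#'   `codebook_a.tsv`, `codebook_b.tsv`, `design.yaml`.
#' @return a validated `del_manifest`.
#' @export
load_manifest <- function(dir) {
  need <- c("blocks_a.tsv", "blocks_b.tsv", "codebook_a.tsv",
            "codebook_b.tsv", "design.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("manifest directory ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                               colClasses = NA)
  cfg <- yaml::read_yaml(file.path(dir, "design.yaml"))
  m <- del_manifest(
    blocks_a = rd("blocks_a.tsv"), blocks_b = rd("blocks_b.tsv"),
    codebook_a = rd("codebook_a.tsv"), codebook_b = rd("codebook_b.tsv"),
    stereo_labels = unlist(cfg$stereo_labels),
    scaffold_mass = cfg$scaffold_mass,
    linkage_deltas = cfg$linkage_deltas %||%
      list(amide = -18.02, triazole = 0),
    scaffold_hbd = cfg$scaffold_hbd %||% 1L,
    scaffold_hba = cfg$scaffold_hba %||% 4L,
    scaffold_logp = cfg$scaffold_logp %||% -0.5,
    d_min = cfg$d_min %||% 3L,
    layout = cfg$layout %||% default_read_layout())
  log_msg("loaded manifest from ", dir, ": ", nrow(m$blocks_a),
          " A blocks, ", nrow(m$blocks_b), " B blocks, ",
          length(m$stereo_labels), " stereoisomers")
  m
}

#' Content hash of a manifest
#'
#' MD5 over the serialised manifest components, used by the pipeline log so
#' decoded outputs are traceable to a design version.
#'
#' @param manifest a `del_manifest`.
#' @return character MD5 digest.
#' @export
manifest_hash <- function(manifest) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.csv(
    rbind(
      data.frame(k = manifest$blocks_a$block_id,
                 v = manifest$blocks_a$chem_class),
      data.frame(k = manifest$blocks_b$block_id,
                 v = manifest$blocks_b$chem_class),
      data.frame(k = manifest$codebook_a$code_id,
                 v = manifest$codebook_a$sequence),
      data.frame(k = manifest$codebook_b$code_id,
                 v = manifest$codebook_b$sequence),
      data.frame(k = "stereo",
                 v = paste(manifest$stereo_labels, collapse = ","))),
    tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}
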