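A_CLASSES <- c("primary-amine", "secondary-amine", "heteroaromatic-amine",
               "ammonia-control")
B_CLASSES <- c("carboxylic-acid", "alkyne")

default_read_layout <- function() {
  list(prefix = "ACGTAC", spacer = "TGCA", suffix = "GTCAGT")
}

#' Construct a DEL design manifest
#'
#' A manifest bundles everything that defines the encoded library: the two
#' building-block registries (set A, coupled to the scaffold first; set B,
#' appended in the second split-and-pool step), the stereoisomer labels, the
#' two barcode codebooks, optional mass/property contributions for
#' drug-likeness annotation, and the fixed read layout used by the simulator
#' and decoder. Stereochemistry is deliberately *not* part of the DNA code:
#' both stereoisomers of a (A, B) pair share one CodeA/CodeB tag and are
#' resolved only at hit validation.
#'
#' @param blocks_a,blocks_b data.frames with columns `block_id`,
#'   `chem_class` and optionally `mass`, `hbd`, `hba`, `logp_contrib`.
#'   Valid A classes: `r paste(A_CLASSES, collapse = ", ")`; valid B
#'   classes: `r paste(B_CLASSES, collapse = ", ")`.
#' @param codebook_a,codebook_b data.frames as returned by
#'   [generate_codebook()]; `code_id`s must coincide with the block ids of
#'   the matching set.
#' @param stereo_labels character vector of stereoisomer labels sharing each
#'   code pair (default `c("R", "S")`).
#' @param scaffold_mass scaffold mass contribution in g/mol (optional,
#'   required for property annotation).
#' @param linkage_deltas named list of mass corrections applied per B-block
#'   chemistry: `amide` for carboxylic-acid couplings (water loss),
#'   `triazole` for alkyne cycloadditions.
#' @param scaffold_hbd,scaffold_hba,scaffold_logp scaffold-level H-bond
#'   donor/acceptor counts and logP offset entering the Lipinski annotation.
#' @param d_min minimum pairwise Hamming distance both codebooks must
#'   satisfy (default 3, the single-error-correcting design).
#' @param layout list with `prefix`, `spacer`, `suffix` DNA strings flanking
#'   the two code slots in every sequencing read.
#' @return validated object of class `del_manifest`.
#' @seealso [load_manifest()], [gbdel_manifest()], [enumerate_library()]
#' @export
del_manifest <- function(blocks_a, blocks_b, codebook_a, codebook_b,
                         stereo_labels = c("R", "S"),
                         scaffold_mass = NULL,
                         linkage_deltas = list(amide = -18.02, triazole = 0),
                         scaffold_hbd = 1L, scaffold_hba = 4L,
                         scaffold_logp = -0.5,
                         d_min = 3L,
                         layout = default_read_layout()) {
  m <- structure(list(
    blocks_a = as.data.frame(blocks_a), blocks_b = as.data.frame(blocks_b),
    codebook_a = as.data.frame(codebook_a),
    codebook_b = as.data.frame(codebook_b),
    stereo_labels = as.character(stereo_labels),
    scaffold_mass = scaffold_mass, linkage_deltas = linkage_deltas,
    scaffold_hbd = scaffold_hbd, scaffold_hba = scaffold_hba,
    scaffold_logp = scaffold_logp,
    d_min = as.integer(d_min), layout = layout), class = "del_manifest")
  validate_manifest(m)
}

check_blocks <- function(blocks, set_label, classes) {
  need <- c("block_id", "chem_class")
  if (!all(need %in% names(blocks)))
    stop("blocks_", tolower(set_label), " must have columns ",
         paste(need, collapse = ", "))
  dup <- blocks$block_id[duplicated(blocks$block_id)]
  if (length(dup))
    stop("duplicate block_id in set ", set_label, ": ",
         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(blocks$chem_class), classes)
  if (length(bad))
    stop("chem_class not valid for set ", set_label, ": ",
         paste(bad, collapse = ", "))
  invisible(blocks)
}

check_codebook <- function(codebook, blocks, set_label, d_min) {
  if (nrow(codebook) != nrow(blocks))
    stop("codebook_", tolower(set_label), " has ", nrow(codebook),
         " codes for ", nrow(blocks), " blocks")
  if (!setequal(codebook$code_id, blocks$block_id))
    stop("codebook_", tolower(set_label),
         " code_ids do not match block_ids of set ", set_label)
  if (length(unique(nchar(codebook$sequence))) != 1L)
    stop("codebook_", tolower(set_label), " sequences differ in length")
  if (!all(grepl("^[ACGT]+$", codebook$sequence)))
    stop("codebook_", tolower(set_label),
         " contains non-ACGT characters")
  h <- min_pairwise_hamming(codebook$sequence)
  if (h$min < d_min)
    stop("codebook_", tolower(set_label), " minimum Hamming distance ",
         h$min, " < d_min ", d_min, " (offending pair: ",
         codebook$code_id[h$pair[1]], ", ", codebook$code_id[h$pair[2]], ")")
  invisible(codebook)
}

#' Validate a design manifest
#'
#' Verifies every manifest invariant: unique block ids, chemistry classes
#' consistent with their set, codebooks matching block registries one-to-one,
#' fixed code length per role, and minimum pairwise Hamming distance at
#' least `d_min` within each codebook. Violations are hard errors naming the
#' offending entries.
#'
#' @param manifest a `del_manifest`.
#' @return the manifest, invisibly, if valid.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "del_manifest"))
  check_blocks(manifest$blocks_a, "A", A_CLASSES)
  check_blocks(manifest$blocks_b, "B", B_CLASSES)
  if (length(manifest$stereo_labels) < 1L ||
      anyDuplicated(manifest$stereo_labels))
    stop("stereo_labels must be a non-empty set of distinct labels")
  check_codebook(manifest$codebook_a, manifest$blocks_a, "A", manifest$d_min)
  check_codebook(manifest$codebook_b, manifest$blocks_b, "B", manifest$d_min)
  with(manifest$layout, stopifnot(is.character(prefix), is.character(spacer),
                                  is.character(suffix)))
  invisible(manifest)
}

#' @export
print.del_manifest <- function(x, ...) {
  cat("DEL design manifest\n")
  cat(sprintf("  building blocks A: %d  (%s)\n", nrow(x$blocks_a),
              paste(sprintf("%s: %d", names(table(x$blocks_a$chem_class)),
                            table(x$blocks_a$chem_class)), collapse = ", ")))
  cat(sprintf("  building blocks B: %d  (%s)\n", nrow(x$blocks_b),
              paste(sprintf("%s: %d", names(table(x$blocks_b$chem_class)),
                            table(x$blocks_b$chem_class)), collapse = ", ")))
  cat(sprintf("  stereoisomers: %s\n",
              paste(x$stereo_labels, collapse = ", ")))
  cat(sprintf("  library size: %d members over %d code pairs\n",
              length(x$stereo_labels) * nrow(x$blocks_a) * nrow(x$blocks_b),
              nrow(x$blocks_a) * nrow(x$blocks_b)))
  cat(sprintf("  codes: %d nt, d_min = %d\n",
              nchar(x$codebook_a$sequence[1]), x$d_min))
  invisible(x)
}

#' Enumerate the combinatorial library
#'
#' Expands the manifest into every encoded compound: one row per
#' (stereoisomer, A block, B block) triple, in deterministic stereo-major
#' order (stereo, then A index, then B index) so outputs are
#' byte-reproducible. Both stereoisomers of a pair carry the same
#' CodeA/CodeB tag, so the number of distinct code pairs is |A| x |B| while
#' the member count is |stereo| x |A| x |B|.
#'
#' @param manifest a validated `del_manifest`.
#' @return data.frame with columns `stereo`, `a_id`, `b_id`, `code_a`,
#'   `code_b`.
#' @export
#' @examples
#' m <- toy_manifest(n_a = 3, n_b = 5)
#' nrow(enumerate_library(m)) # 2 * 3 * 5
enumerate_library <- function(manifest) {
  validate_manifest(manifest)
  a <- manifest$blocks_a$block_id
  b <- manifest$blocks_b$block_id
  g <- expand.grid(b_id = b, a_id = a, stereo = manifest$stereo_labels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(stereo = g$stereo, a_id = g$a_id, b_id = g$b_id,
             code_a = g$a_id, code_b = g$b_id, stringsAsFactors = FALSE)
}

member_key <- function(stereo, a_id, b_id) paste(stereo, a_id, b_id, sep = "|")

#' Annotate library members with physicochemical properties
#'
#' Computes per-member molecular weight as scaffold mass + A contribution +
#' B contribution + the linkage correction for the B-block chemistry
#' (amide condensation or triazole cycloaddition), sums H-bond donor/
#' acceptor and logP contributions with the scaffold offsets, and evaluates
#' the Lipinski rule-of-five conjunction (MW <= 500, HBD <= 5, HBA <= 10,
#' logP <= 5; all boundaries inclusive).
#'
#' @param manifest a `del_manifest` whose blocks carry `mass`, `hbd`, `hba`,
#'   `logp_contrib` columns. If the blocks carry no property columns the
#'   records are returned flagged unavailable (`available = FALSE`); if
#'   masses are present but `scaffold_mass` is missing, that is an error.
#' @return data.frame with one row per library member: member key columns,
#'   `mw`, `hbd`, `hba`, `logp`, `ro5_pass`, `available`.
#' @export
annotate_properties <- function(manifest) {
  members <- enumerate_library(manifest)
  ba <- manifest$blocks_a
  bb <- manifest$blocks_b
  have_props <- all(c("mass", "hbd", "hba", "logp_contrib") %in% names(ba)) &&
    all(c("mass", "hbd", "hba", "logp_contrib") %in% names(bb)) &&
    !anyNA(ba$mass) && !anyNA(bb$mass)
  if (!have_props) {
    members$mw <- NA_real_
    members$hbd <- NA_integer_
    members$hba <- NA_integer_
    members$logp <- NA_real_
    members$ro5_pass <- NA
    members$available <- FALSE
    return(members)
  }
  if (is.null(manifest$scaffold_mass))
    stop("block masses are present but the manifest has no scaffold_mass")
  ia <- match(members$a_id, ba$block_id)
  ib <- match(members$b_id, bb$block_id)
  delta <- ifelse(bb$chem_class[ib] == "carboxylic-acid",
                  manifest$linkage_deltas$amide %||% 0,
                  manifest$linkage_deltas$triazole %||% 0)
  members$mw <- manifest$scaffold_mass + ba$mass[ia] + bb$mass[ib] + delta
  members$hbd <- manifest$scaffold_hbd + ba$hbd[ia] + bb$hbd[ib]
  members$hba <- manifest$scaffold_hba + ba$hba[ia] + bb$hba[ib]
  members$logp <- manifest$scaffold_logp + ba$logp_contrib[ia] +
    bb$logp_contrib[ib]
  members$ro5_pass <- members$mw <= 500 & members$hbd <= 5 &
    members$hba <= 10 & members$logp <= 5
  members$available <- TRUE
  members
}
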