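JET_COLOURS <- c("#00007F", "blue", "#007FFF", "cyan", "#7FFF7F",
                 "yellow", "#FF7F00", "red", "#7F0000")

#' Fingerprint plot of a decoded selection
#'
#' Visualises a CodeA-by-CodeB count fingerprint either as the classic
#' tridimensional plot (x, y = code indices, z = sequence counts) or as the
#' more compact pseudo-2D representation: a CodeA vs CodeB scatter of
#' non-zero combinations colour-mapped (jet scale) by count. Plots are
#' advisory; quantitative conclusions should be drawn from the ranked
#' tables, not pixels.
#'
#' @param x a `del_counts` (or `del_ef`, plotted on its `count` column).
#' @param representation `"pseudo2d"` or `"3d"`.
#' @param file optional output path; pseudo-2D plots are saved with
#'   [ggplot2::ggsave()], 3D plots through [grDevices::png()].
#' @param log_scale colour non-zero counts on log10 (pseudo-2D only)?
#' @return the ggplot object (pseudo2d) or, for 3d/file output, the input
#'   invisibly.
#' @export
fingerprint_plot <- function(x, representation = c("pseudo2d", "3d"),
                             file = NULL, log_scale = TRUE) {
  representation <- match.arg(representation)
  if (inherits(x, "del_ef")) {
    a_ids <- unique(x$code_a)
    b_ids <- unique(x$code_b)
    m <- matrix(x$count, length(a_ids), length(b_ids),
                dimnames = list(a_ids, b_ids))
    x <- del_counts(m)
  }
  stopifnot(inherits(x, "del_counts"))
  if (x$tcs == 0) stop("cannot plot an empty fingerprint (TCs = 0)")
  if (representation == "3d") {
    draw <- function() {
      graphics::persp(seq_len(nrow(x$counts)), seq_len(ncol(x$counts)),
                      x$counts, xlab = "CodeA", ylab = "CodeB",
                      zlab = "sequence counts", theta = 35, phi = 25,
                      expand = 0.6, col = "grey85", border = NA,
                      shade = 0.6, ticktype = "detailed")
    }
    if (!is.null(file)) {
      grDevices::png(file, width = 1200, height = 900, res = 150)
      on.exit(grDevices::dev.off())
    }
    draw()
    return(invisible(x))
  }
  nz <- which(x$counts > 0, arr.ind = TRUE)
  df <- data.frame(code_a = nz[, 1], code_b = nz[, 2],
                   count = x$counts[nz])
  df$shade <- if (log_scale) log10(df$count) else df$count
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$code_a, y = .data$code_b,
                                        colour = .data$shade)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_gradientn(
      colours = JET_COLOURS,
      name = if (log_scale) "log10 counts" else "counts") +
    ggplot2::labs(x = "CodeA", y = "CodeB") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
    return(invisible(x))
  }
  p
}

#' Run the full selection-analysis pipeline
#'
#' Executes design validation, optional selection simulation, decoding,
#' enrichment analysis and reporting in one call, writing a reproducible
#' artifact bundle. Any stage failure aborts with the stage name. Tables
#' are bit-identical across re-runs with the same configuration and seed;
#' the log records the manifest content hash so decoded output is traceable
#' to a design version.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `manifest_dir` (or a `del_manifest` under `manifest`), `out_dir`,
#'   optional `scenario` (a [scenario_preset()] name, simulated when
#'   `reads` is absent), optional `reads` (existing FASTQ), `seed`
#'   (default 1), `depth` (scenario depth override), `max_mismatch`
#'   (default 1), `baseline` (default `"uniform"`), `ef_min` (10),
#'   `count_min` (3), `plot` (default TRUE, pseudo-2D PNG).
#' @return invisible list with the manifest, `counts` (`del_counts`),
#'   `ef` (`del_ef`), `hits`, `summary`, and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "pipeline.log")
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  manifest <- stage("design", {
    m <- if (!is.null(config[["manifest"]]))
           validate_manifest(config[["manifest"]])
         else load_manifest(config[["manifest_dir"]] %||%
                            stop("config needs manifest_dir or manifest"))
    log_msg("design: ", nrow(m$blocks_a), " x ", nrow(m$blocks_b),
            " grid, manifest hash ", manifest_hash(m), file = log_file)
    m
  })

  reads <- config[["reads"]]
  if (is.null(reads)) {
    reads <- file.path(out_dir, "reads.fastq")
    stage("simulate", {
      sc <- scenario_preset(config$scenario %||% "sp_selection",
                            manifest = manifest, seed = seed,
                            depth = config$depth)
      cfg <- if (inherits(sc$cfg, "del_seqcfg")) sc$cfg else sc$cfg[[1]]
      cap <- simulate_capture(sc$truth, sc$mode_sp, seed = seed)
      sequence_reads(cap, manifest, cfg, fastq = reads)
      log_msg("simulate: scenario ", config$scenario %||% "sp_selection",
              ", depth ", cfg$depth, ", seed ", seed, file = log_file)
    })
  }

  counts <- stage("decode", {
    x <- decode_fastq(reads, manifest,
                      max_mismatch = config$max_mismatch %||% 1L)
    write_counts(x, file.path(out_dir, "counts.tsv"))
    s <- summary(x)
    log_msg("decode: TCs = ", s$tcs, ", ACs = ", s$acs_display,
            ", discarded ", sum(s$discarded), "/", s$n_reads,
            file = log_file)
    x
  })

  ef <- stage("enrich", {
    e <- enrichment_factors(counts, baseline = config$baseline %||% "uniform")
    write.table(as.data.frame(e)[e$count > 0, ],
                file.path(out_dir, "ef.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    e
  })
  hits <- call_hits(ef, ef_min = config$ef_min %||% 10,
                    count_min = config$count_min %||% 3)

  stage("report", {
    s <- summary(counts)
    jsonlite::write_json(
      list(tcs = s$tcs, acs = s$acs, acs_display = s$acs_display,
           discarded = as.list(s$discarded),
           discard_fraction = s$discard_fraction,
           n_hits = nrow(hits),
           top_hits = head(hits[, c("code_a", "code_b", "count", "ef")],
                           10L)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$plot %||% TRUE) && counts$tcs > 0)
      fingerprint_plot(counts, "pseudo2d",
                       file = file.path(out_dir, "fingerprint.png"))
    log_msg("report: ", nrow(hits), " hits at ef >= ",
            config$ef_min %||% 10, file = log_file)
  })

  invisible(list(manifest = manifest, counts = counts, ef = ef,
                 hits = hits, summary = summary(counts),
                 paths = list(out_dir = out_dir, reads = reads,
                              counts = file.path(out_dir, "counts.tsv"),
                              ef = file.path(out_dir, "ef.tsv"),
                              summary = file.path(out_dir, "summary.json"),
                              log = log_file)))
}
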