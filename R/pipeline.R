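#' Validate a pipeline configuration
#'
#' A configuration is a nested list (typically read from a YAML file) with
#' blocks:
#'
#' * `library` — [library_design()] fields (all optional; defaults are the
#'   3-codon 331/332/333 design).
#' * `input` — exactly one of `fastq` (per-arm named lists of
#'   passage-label -> FASTQ path) or `simulate` (simulator settings:
#'   `read_depth`, `bottleneck`, `n_passages`, `groels_buffer`,
#'   `hitchhiker_rate`, `hitchhiker_boost`).
#' * `analysis` — `min_input_reads` (default 10), `lowered_bound`
#'   (default -1.0), `heatmap_mode` (`literal`/`centered`), `arms`
#'   (arms intersected for the positive set; default all arms).
#' * `run` — `seed`, `outdir`.
#'
#' @param config list or path to a YAML file.
#' @return the validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  lib <- config$library
  design <- library_design(
    n_positions = lib$n_positions %||% 3L,
    position_labels = lib$position_labels %||% c(331L, 332L, 333L),
    wildtype_protein = lib$wildtype_protein %||% "DRA",
    flank_up = lib$flank_up %||% formals(library_design)$flank_up,
    flank_down = lib$flank_down %||% formals(library_design)$flank_down)
  inp <- config$input
  has_fastq <- !is.null(inp$fastq)
  has_sim <- !is.null(inp$simulate)
  if (has_fastq == has_sim)
    stop("config must have exactly one of input$fastq / input$simulate",
         call. = FALSE)
  ana <- config$analysis
  analysis <- list(
    min_input_reads = ana$min_input_reads %||% 10,
    lowered_bound = ana$lowered_bound %||% -1.0,
    heatmap_mode = ana$heatmap_mode %||% "literal",
    arms = ana$arms)
  stopifnot(is.finite(analysis$min_input_reads),
            is.finite(analysis$lowered_bound),
            analysis$heatmap_mode %in% c("literal", "centered"))
  run <- config$run
  structure(list(design = design, input = inp, analysis = analysis,
                 seed = run$seed %||% 1L,
                 outdir = run$outdir %||% stop("run$outdir is required",
                                               call. = FALSE)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full selection-analysis pipeline
#'
#' simulate (or count FASTQ) -> detection threshold -> fitness -> arm
#' comparison -> enrichment matrix, writing a result bundle to
#' `run$outdir`: per-arm count and fitness TSVs, a per-arm summary TSV, the
#' enrichment-matrix TSV, and a JSON manifest (config echo, seed, package
#' version, read/variant counts at every filtering stage). Identical
#' config + seed produces an identical bundle.
#'
#' @param config a [pipeline_config()], raw list, or YAML path.
#' @return invisibly, a `pancs_bundle` list: `dir`, `fits` (per arm),
#'   `comparison` (when two arms), `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  design <- cfg$design

  tables <- tryCatch(
    stage_tables(cfg, design),
    error = function(e) stop("input stage failed: ", conditionMessage(e),
                             call. = FALSE))
  arms <- names(tables)

  fits <- list()
  for (a in arms) {
    fits[[a]] <- tryCatch(
      pancs_fit(tables[[a]], min_input_reads = cfg$analysis$min_input_reads,
                lowered_bound = cfg$analysis$lowered_bound),
      error = function(e) stop("fitness stage failed for arm '", a, "': ",
                               conditionMessage(e), call. = FALSE))
    write_count_table(tables[[a]],
                      file.path(cfg$outdir, paste0("counts_", a, ".tsv")))
    write_fitness_tsv(fits[[a]],
                      file.path(cfg$outdir, paste0("fitness_", a, ".tsv")))
  }

  comparison <- NULL
  if (length(arms) == 2L)
    comparison <- compare_arms(fits[[1L]], fits[[2L]])

  heat_arms <- cfg$analysis$arms %||% arms
  pos <- positive_set(fits[heat_arms])
  starting <- fits[[heat_arms[1L]]]$records$variant
  enr <- enrichment_matrix(pos, starting[!has_stop(starting)], design,
                           mode = cfg$analysis$heatmap_mode)
  write_enrichment_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))

  summ <- do.call(rbind, lapply(arms, function(a) {
    s <- summary(fits[[a]])
    data.frame(arm = a, n_analyzed = s$n_analyzed,
               n_depleted = s$n_depleted, n_positive = s$n_positive,
               fraction_positive = s$fraction_positive,
               fraction_lowered_assembly = s$fraction_lowered_assembly,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(summ, file.path(cfg$outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "pancseq",
    version = as.character(utils::packageVersion("pancseq")),
    seed = cfg$seed,
    config = list(
      library = cfg$design[c("n_positions", "position_labels",
                             "wildtype_protein", "flank_up", "flank_down")],
      input = cfg$input, analysis = cfg$analysis),
    stages = lapply(stats::setNames(arms, arms), function(a) {
      tab <- tables[[a]]
      list(raw_reads = as.list(tab$totals),
           accepted = as.list(colSums(tab$counts)),
           rejected = as.list(colSums(tab$rejected)),
           detected = unname(fits[[a]]$census["n_detected"]),
           retained = unname(fits[[a]]$census["n_retained"]),
           dropped = unname(fits[[a]]$census["n_dropped"]))
    }),
    positive_set_arms = heat_arms,
    n_dual_positive = length(pos))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(list(dir = cfg$outdir, fits = fits,
                           comparison = comparison, enrichment = enr,
                           manifest = manifest),
                      class = "pancs_bundle"))
}

## Build per-arm count tables from whichever input block is present.
stage_tables <- function(cfg, design) {
  if (!is.null(cfg$input$fastq)) {
    fq <- cfg$input$fastq
    # allow a single unnamed arm given directly as passage -> path
    if (!is.list(fq[[1L]])) fq <- list(arm1 = fq)
    lapply(fq, function(files)
      count_fastq(unlist(files), design,
                  variants = enumerate_protein_variants(design)))
  } else {
    s <- cfg$input$simulate
    truth <- ground_truth(design, seed = cfg$seed,
                          groels_buffer = s$groels_buffer %||% 0.5)
    ex <- simulate_experiment(
      design = design, truth = truth,
      n_passages = s$n_passages %||% 3L,
      bottleneck = s$bottleneck %||% 1e5,
      read_depth = s$read_depth %||% 2e6,
      hitchhiker_rate = s$hitchhiker_rate %||% 0,
      hitchhiker_boost = s$hitchhiker_boost %||% 30,
      seed = cfg$seed)
    list(minus = ex$minus$table, plus = ex$plus$table)
  }
}

#' Human-readable summary of a result bundle
#'
#' Prints the per-arm census (analyzed, depleted, positive fraction,
#' predicted lowered assembly) and the top enriched variants by fitness.
#'
#' @param bundle a `pancs_bundle` from [run_pipeline()], or a bundle
#'   directory path.
#' @param top_k number of top variants to list per arm. Default 10.
#' @return the summary text, invisibly; printed as a side effect.
#' @export
report_summary <- function(bundle, top_k = 10) {
  if (is.character(bundle)) {
    need <- c("summary.tsv", "manifest.json")
    missing <- need[!file.exists(file.path(bundle, need))]
    if (length(missing))
      stop("incomplete bundle: missing ", paste(missing, collapse = ", "),
           call. = FALSE)
    summ <- utils::read.delim(file.path(bundle, "summary.tsv"))
    fit_files <- list.files(bundle, "^fitness_.*\\.tsv$", full.names = TRUE)
    tops <- lapply(fit_files, function(f) {
      df <- utils::read.delim(f)
      df <- df[order(-df$fitness), ]
      utils::head(df$variant[!is.na(df$fitness)], top_k)
    })
    names(tops) <- sub("^fitness_(.*)\\.tsv$", "\\1", basename(fit_files))
  } else {
    stopifnot(inherits(bundle, "pancs_bundle"))
    summ <- do.call(rbind, lapply(names(bundle$fits), function(a) {
      s <- summary(bundle$fits[[a]])
      data.frame(arm = a, n_analyzed = s$n_analyzed,
                 n_depleted = s$n_depleted, n_positive = s$n_positive,
                 fraction_positive = s$fraction_positive,
                 fraction_lowered_assembly = s$fraction_lowered_assembly)
    }))
    tops <- lapply(bundle$fits, function(f) {
      co <- sort(coef(f), decreasing = TRUE, na.last = NA)
      names(utils::head(co, top_k))
    })
  }
  lines <- character(0)
  for (i in seq_len(nrow(summ))) {
    r <- summ[i, ]
    lines <- c(lines, sprintf(
      "arm %s: %d analyzed, %d depleted, %.1f%% positive, %.1f%% predicted lowered assembly",
      r$arm, r$n_analyzed, r$n_depleted, 100 * r$fraction_positive,
      100 * r$fraction_lowered_assembly))
    lines <- c(lines, sprintf("  top enriched: %s",
                              paste(tops[[r$arm]], collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
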