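#' Per-passage read fractions
#'
#' Read fraction of every retained variant in one passage: count divided by
#' the column total over retained variants. Fractions sum to 1.
#'
#' @param table a [count_table()].
#' @param passage passage label.
#' @return named numeric vector.
#' @export
fractions <- function(table, passage) {
  stopifnot(inherits(table, "count_table"))
  if (!passage %in% table$passages)
    stop("no passage '", passage, "' in table", call. = FALSE)
  col <- stats::setNames(table$counts[, passage], rownames(table$counts))
  tot <- sum(col)
  if (tot <= 0) stop("passage '", passage, "' has zero total reads",
                     call. = FALSE)
  col / tot
}

#' Log10 frequency-ratio fitness score
#'
#' `log10(f_final / f_input)`: 0 means unchanged relative abundance, +1 a
#' tenfold enrichment, -1 a tenfold de-enrichment. A variant absent from
#' the final passage (`f_final = 0`) has no finite score and is returned
#' as `NA` — the explicit "completely depleted" class — rather than as
#' -Inf; no pseudocounts are used.
#'
#' @param f_input,f_final read fractions in the input and final passages
#'   (vectorized). `f_input` must be positive (guaranteed upstream by the
#'   detection threshold).
#' @return numeric vector; `NA` where depleted.
#' @examples
#' fitness_score(0.01, 0.001)  # -1
#' @export
fitness_score <- function(f_input, f_final) {
  if (any(f_input <= 0))
    stop("f_input must be positive (apply the detection threshold first)",
         call. = FALSE)
  stopifnot(all(f_final >= 0))
  ifelse(f_final > 0, log10(f_final / f_input), NA_real_)
}

#' Fold propagation of a phage culture
#'
#' Output phage divided by input phage for one infection culture — the
#' per-passage measure of a variant pool's selective advantage (input is
#' typically 1e5 phage).
#'
#' @param output_titer,input_titer phage counts.
#' @return numeric.
#' @export
fold_propagation <- function(output_titer, input_titer) {
  if (any(input_titer <= 0)) stop("input titer must be positive",
                                  call. = FALSE)
  output_titer / input_titer
}

#' Fit per-variant selection fitness from a count table
#'
#' The central estimator: from a variant-by-passage read-count table it
#' applies the input detection threshold, computes per-passage frequency
#' trajectories, scores each retained variant by
#' `log10(f_final / f_input)`, and classifies it as
#'
#' * `depleted` — zero reads in the final passage,
#' * `positive` — fitness > 0 (enriched relative to the input pool),
#' * `negative` — fitness <= 0 and not depleted.
#'
#' A variant is predicted to have lowered assembly efficiency when it is
#' depleted or its fitness is -1.0 or lower (a tenfold or greater drop in
#' relative abundance); the bound is inclusive.
#'
#' @param table a [count_table()] with an `input` passage.
#' @param min_input_reads detection threshold on input reads (default 10);
#'   set to 0 if the table is already thresholded.
#' @param final final passage label; default the last passage present.
#' @param lowered_bound fitness bound for the lowered-assembly call
#'   (default -1.0, inclusive).
#' @return an object of class `pancs_fit`: list with `records` (one row
#'   per retained variant), `trajectory` (fraction matrix), `census`,
#'   `min_input_reads`, `final`, `table`.
#' @seealso [summary.pancs_fit()], [compare_arms()], [positive_set()]
#' @export
pancs_fit <- function(table, min_input_reads = 10, final = NULL,
                      lowered_bound = -1.0) {
  stopifnot(inherits(table, "count_table"))
  thr <- apply_detection_threshold(table, min_input_reads)
  tab <- thr$table
  if (nrow(tab$counts) == 0L)
    stop("no variants pass the detection threshold", call. = FALSE)
  if (is.null(final)) final <- tab$passages[length(tab$passages)]
  stopifnot(final %in% tab$passages, final != "input")
  traj <- vapply(tab$passages, function(p) fractions(tab, p),
                 numeric(nrow(tab$counts)))
  dimnames(traj) <- dimnames(tab$counts)
  f_in <- traj[, "input"]
  f_fin <- traj[, final]
  fit <- fitness_score(f_in, f_fin)
  depleted <- tab$counts[, final] == 0
  cls <- ifelse(depleted, "depleted",
                ifelse(fit > 0, "positive", "negative"))
  records <- data.frame(
    variant = rownames(tab$counts),
    contains_stop = has_stop(rownames(tab$counts)),
    f_input = f_in,
    f_final = f_fin,
    fitness = fit,
    outcome_class = cls,
    lowered_assembly_predicted = depleted | (!is.na(fit) &
                                               fit <= lowered_bound),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(records = records, trajectory = traj,
                 census = thr$census, min_input_reads = min_input_reads,
                 final = final, lowered_bound = lowered_bound,
                 table = tab),
            class = "pancs_fit")
}

#' @export
print.pancs_fit <- function(x, ...) {
  s <- summary(x)
  cat("Selection fitness fit (", x$final, " vs input)\n", sep = "")
  cat("  variants analyzed: ", s$n_analyzed,
      " (threshold: >=", x$min_input_reads, " input reads)\n", sep = "")
  cat("  depleted: ", s$n_depleted,
      "  positive: ", s$n_positive,
      " (", sprintf("%.1f%%", 100 * s$fraction_positive), ")\n", sep = "")
  cat("  predicted lowered assembly: ",
      sprintf("%.1f%%", 100 * s$fraction_lowered_assembly), "\n", sep = "")
  invisible(x)
}

#' Fitness scores of a fit
#'
#' @param object a [pancs_fit()].
#' @param ... ignored.
#' @return named numeric vector of fitness scores (`NA` = depleted).
#' @export
coef.pancs_fit <- function(object, ...) {
  stats::setNames(object$records$fitness, object$records$variant)
}

#' Summarize a selection arm
#'
#' Counts and fractions over the analyzed variants: depleted, positive,
#' and predicted-lowered-assembly (depleted or fitness at or below the
#' bound).
#'
#' @param object a [pancs_fit()].
#' @param ... ignored.
#' @return a `selection_summary` list: `n_analyzed`, `n_depleted`,
#'   `n_positive`, `fraction_positive`, `fraction_lowered_assembly`.
#' @export
summary.pancs_fit <- function(object, ...) {
  r <- object$records
  if (nrow(r) == 0L) stop("empty record set", call. = FALSE)
  structure(list(
    n_analyzed = nrow(r),
    n_depleted = sum(r$outcome_class == "depleted"),
    n_positive = sum(r$outcome_class == "positive"),
    fraction_positive = mean(r$outcome_class == "positive"),
    fraction_lowered_assembly = mean(r$lowered_assembly_predicted)
  ), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("n analyzed:", x$n_analyzed,
      "| depleted:", x$n_depleted,
      "| positive:", x$n_positive,
      sprintf("(%.1f%%)", 100 * x$fraction_positive),
      "| lowered assembly:",
      sprintf("%.1f%%", 100 * x$fraction_lowered_assembly), "\n")
  invisible(x)
}

#' Plot variant frequency trajectories
#'
#' One line per variant across passages on a log scale, the standard
#' spaghetti view of a selection. Zero fractions are clamped to the
#' detection floor (`min_input_reads` / input depth), drawn as a dotted
#' line, so depleted trajectories terminate there.
#'
#' @param x a [pancs_fit()].
#' @param max_lines at most this many variants are drawn (random subset,
#'   fixed order), keeping the plot legible. Default 500.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pancs_fit <- function(x, max_lines = 500, ...) {
  traj <- x$trajectory
  floor_f <- x$min_input_reads / max(sum(x$table$counts[, "input"]), 1)
  if (floor_f <= 0) floor_f <- 1e-7
  traj[traj < floor_f] <- floor_f
  if (nrow(traj) > max_lines)
    traj <- traj[seq(1L, nrow(traj), length.out = max_lines), , drop = FALSE]
  cls <- x$records$outcome_class[match(rownames(traj), x$records$variant)]
  col <- ifelse(cls == "positive", grDevices::rgb(0.8, 0.2, 0.2, 0.5),
                grDevices::rgb(0.4, 0.4, 0.4, 0.25))
  graphics::matplot(t(traj), type = "l", lty = 1, col = col, log = "y",
                    xaxt = "n", xlab = "passage",
                    ylab = "fraction of sequencing reads", ...)
  graphics::axis(1, at = seq_along(x$table$passages),
                 labels = x$table$passages)
  graphics::abline(h = floor_f, lty = 3)
  invisible(x)
}

#' Write per-variant fitness records as TSV
#'
#' One row per analyzed variant: trajectory fractions, fitness score,
#' outcome class, and the lowered-assembly prediction — the
#' machine-readable per-arm variant table.
#'
#' @param fit a [pancs_fit()].
#' @param path output TSV path.
#' @export
write_fitness_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "pancs_fit"))
  traj <- as.data.frame(fit$trajectory)
  names(traj) <- paste0("frac_", names(traj))
  df <- cbind(fit$records[, c("variant", "contains_stop")], traj,
              fit$records[, c("fitness", "outcome_class",
                              "lowered_assembly_predicted")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare the -GroELS and +GroELS selection arms
#'
#' Both fits must cover the same retained variant set (one input library
#' split across conditions). Reports the ratio of positive fractions, the
#' change in depleted counts, and the variants rescued by the chaperonin
#' (depleted without GroELS but not with it).
#'
#' @param fit_minus,fit_plus [pancs_fit()] objects for the two arms.
#' @return an `arm_comparison` list.
#' @export
compare_arms <- function(fit_minus, fit_plus) {
  stopifnot(inherits(fit_minus, "pancs_fit"), inherits(fit_plus, "pancs_fit"))
  vm <- fit_minus$records$variant
  vp <- fit_plus$records$variant
  if (!identical(sort(vm), sort(vp)))
    stop("arms were analyzed over different variant sets", call. = FALSE)
  sm <- summary(fit_minus); sp <- summary(fit_plus)
  dm <- vm[fit_minus$records$outcome_class == "depleted"]
  dp <- vp[fit_plus$records$outcome_class == "depleted"]
  structure(list(
    summary_minus = sm, summary_plus = sp,
    positive_ratio = sp$fraction_positive / sm$fraction_positive,
    depleted_change = sp$n_depleted - sm$n_depleted,
    rescued = sort(setdiff(dm, dp)),
    lost = sort(setdiff(dp, dm))
  ), class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat("-GroELS: "); print(x$summary_minus)
  cat("+GroELS: "); print(x$summary_plus)
  cat("positive-fraction ratio (+/-):", signif(x$positive_ratio, 3), "\n")
  cat("depleted change (+ minus -):", x$depleted_change,
      "| rescued variants:", length(x$rescued), "\n")
  invisible(x)
}
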