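#' Variant-by-passage read-count table
#'
#' The central container of the pipeline: a matrix of read counts with one
#' row per protein-level variant and one column per passage (`input`, `P1`,
#' `P2`, ...), together with per-passage totals and a tally of reads
#' rejected during extraction, broken down by reason. Per passage,
#' `colSums(counts) + colSums(rejected)` equals the raw read count.
#'
#' @param design a [library_design()].
#' @param counts integer matrix, rownames = protein variant strings,
#'   colnames = passage labels.
#' @param rejected optional integer matrix (reason x passage) of rejected
#'   reads; defaults to all-zero.
#' @return an object of class `count_table`.
#' @export
count_table <- function(design, counts, rejected = NULL) {
  stopifnot(inherits(design, "library_design"),
            is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  storage.mode(counts) <- "double"
  if (is.null(rejected)) {
    rejected <- matrix(0, nrow = length(REJECT_REASONS), ncol = ncol(counts),
                       dimnames = list(REJECT_REASONS, colnames(counts)))
  }
  stopifnot(identical(colnames(rejected), colnames(counts)),
            all(rejected >= 0))
  structure(list(
    design = design,
    passages = colnames(counts),
    counts = counts,
    totals = colSums(counts) + colSums(rejected),
    rejected = rejected
  ), class = "count_table")
}

REJECT_REASONS <- c("flank_not_found", "bad_spacing", "n_in_window",
                    "untranslatable")

#' @export
print.count_table <- function(x, ...) {
  cat("Variant count table: ", nrow(x$counts), " variants x ",
      length(x$passages), " passages (",
      paste(x$passages, collapse = ", "), ")\n", sep = "")
  acc <- colSums(x$counts)
  rej <- colSums(x$rejected)
  m <- rbind(accepted = acc, rejected = rej, total = x$totals)
  print(m)
  invisible(x)
}

#' Write / read a count table as TSV
#'
#' The TSV has a `variant` column followed by one column per passage.
#' The round trip is lossless for integer counts. Rejected-read tallies are
#' written to a companion `<path>.rejects.tsv` (reason x passage) and read
#' back if present.
#'
#' @param table a [count_table()].
#' @param path output TSV path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(variant = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rej <- data.frame(reason = rownames(table$rejected), table$rejected,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(rej, paste0(path, ".rejects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param design the [library_design()] the table belongs to.
#' @export
read_count_table <- function(path, design) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$variant
  rej <- NULL
  rpath <- paste0(path, ".rejects.tsv")
  if (file.exists(rpath)) {
    rdf <- utils::read.delim(rpath, check.names = FALSE,
                             stringsAsFactors = FALSE)
    rej <- as.matrix(rdf[, -1L, drop = FALSE])
    rownames(rej) <- rdf$reason
  }
  count_table(design, counts, rejected = rej)
}

#' Apply the input-library detection threshold
#'
#' Retains variants seen in the input passage with at least
#' `min_input_reads` reads (default 10, the detection threshold used for
#' the 9261-member saturation library, of which 7547 passed in the
#' original selection). Downstream fitness analysis sees only retained
#' variants.
#'
#' @param table a [count_table()] with an `input` passage.
#' @param min_input_reads minimum input read count (default 10).
#' @return list with `table` (filtered) and `census`
#'   (`n_detected`, `n_retained`, `n_dropped`).
#' @export
apply_detection_threshold <- function(table, min_input_reads = 10) {
  stopifnot(inherits(table, "count_table"))
  if (!"input" %in% table$passages)
    stop("count table has no 'input' passage", call. = FALSE)
  inp <- table$counts[, "input"]
  keep <- inp >= min_input_reads
  detected <- sum(inp > 0)
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  out <- count_table(table$design, out$counts, rejected = table$rejected)
  list(table = out,
       census = c(n_detected = detected,
                  n_retained = sum(keep),
                  n_dropped = detected - sum(keep & inp > 0)))
}
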