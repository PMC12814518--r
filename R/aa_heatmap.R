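#' Variants with positive fitness across arms
#'
#' Intersection of the positive-fitness variants of one or more selection
#' arms, with stop-codon-containing sequences excluded (they enter
#' counting and fitness but not residue-level enrichment analysis).
#'
#' @param fits a [pancs_fit()] or a list of them (e.g. the two GroELS
#'   arms).
#' @return sorted character vector of variant strings.
#' @export
positive_set <- function(fits) {
  if (inherits(fits, "pancs_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("no arms given", call. = FALSE)
  sets <- lapply(fits, function(f) {
    stopifnot(inherits(f, "pancs_fit"))
    r <- f$records
    r$variant[r$outcome_class == "positive" & !r$contains_stop]
  })
  sort(Reduce(intersect, sets))
}

## Occurrences of each amino acid at each position (plus pooled "total")
## among a set of variant strings. Rows: 20 amino acids; stops excluded.
aa_occurrences <- function(variants, design) {
  np <- design$n_positions
  m <- matrix(0L, nrow = 20L, ncol = np + 1L,
              dimnames = list(AA_ALPHABET_20,
                              c(as.character(design$position_labels),
                                "total")))
  if (length(variants) == 0L) return(m)
  aa <- do.call(rbind, strsplit(variants, ""))
  for (p in seq_len(np)) {
    t <- table(factor(aa[, p], levels = AA_ALPHABET_20))
    m[, p] <- as.integer(t)
  }
  m[, np + 1L] <- rowSums(m[, seq_len(np), drop = FALSE])
  m
}

#' Per-residue amino-acid enrichment matrix
#'
#' For each mutagenized position and amino acid, the log10 ratio of the
#' amino acid's occurrences among positive-fitness variants to its
#' occurrences among all starting (detected) variants; the `total` column
#' pools occurrences over all positions, so a variant contributes once per
#' position-slot. Because the positive set is a subset of the starting
#' set, every defined cell of this literal count ratio is <= 0; cells where
#' the amino acid never occurs in the positive set are the
#' "crossed-out" zero-occurrence sentinel (`NA` + mask), and cells absent
#' even from the starting library are marked not-in-library.
#'
#' `mode = "centered"` subtracts the global log10 ratio of set sizes
#' (occurrence totals), so 0 means "enriched exactly as the average
#' residue" and cells can be positive — often easier to read as a heat map.
#'
#' @param positive character vector of positive variants (subset of
#'   `starting`), e.g. from [positive_set()].
#' @param starting character vector of all detected starting variants.
#' @param design a [library_design()].
#' @param mode `"literal"` (count ratio, all cells <= 0) or `"centered"`.
#' @return an `enrichment_matrix`: numeric matrix (20 amino acids x
#'   positions + total) with attributes `zero_occurrence` and
#'   `not_in_library` (logical masks), `mode`, `n_positive`, `n_starting`.
#' @export
enrichment_matrix <- function(positive, starting, design,
                              mode = c("literal", "centered")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "library_design"), length(starting) > 0)
  positive <- setdiff(positive, positive[has_stop(positive)])
  starting <- setdiff(starting, starting[has_stop(starting)])
  if (!all(positive %in% starting))
    stop("positive set must be a subset of the starting set", call. = FALSE)
  num <- aa_occurrences(positive, design)
  den <- aa_occurrences(starting, design)
  score <- matrix(NA_real_, nrow(num), ncol(num), dimnames = dimnames(num))
  defined <- num > 0 & den > 0
  score[defined] <- log10(num[defined] / den[defined])
  if (mode == "centered") {
    offset <- log10(length(positive) / length(starting))
    score[defined] <- score[defined] - offset
  }
  structure(score,
            zero_occurrence = num == 0 & den > 0,
            not_in_library = den == 0,
            mode = mode,
            n_positive = length(positive),
            n_starting = length(starting),
            class = c("enrichment_matrix", "matrix"))
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("Amino-acid enrichment matrix (mode: ", attr(x, "mode"),
      "; ", attr(x, "n_positive"), " positive / ",
      attr(x, "n_starting"), " starting variants)\n", sep = "")
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  print(round(m, 3))
  nz <- sum(attr(x, "zero_occurrence"))
  if (nz > 0) cat(nz, "zero-occurrence (crossed-out) cells shown as NA\n")
  invisible(x)
}

#' @export
plot.enrichment_matrix <- function(x, ...) {
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  zl <- range(m, na.rm = TRUE)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m)))],
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  zlim = zl, xaxt = "n", yaxt = "n",
                  xlab = "position", ylab = "amino acid", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2)
  zo <- attr(x, "zero_occurrence")[rev(seq_len(nrow(m))), , drop = FALSE]
  idx <- which(t(zo), arr.ind = TRUE)
  if (nrow(idx) > 0)
    graphics::points(idx[, 1], idx[, 2], pch = 4, cex = 1.2)
  invisible(x)
}

#' Write an enrichment matrix as TSV
#'
#' Zero-occurrence cells are rendered `NA:zero_occurrence`, cells absent
#' from the starting library `NA:not_in_library`.
#'
#' @param mat an [enrichment_matrix()].
#' @param path output TSV path.
#' @export
write_enrichment_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "enrichment_matrix"))
  chr <- matrix(formatC(unclass(mat), format = "g", digits = 6),
                nrow(mat), ncol(mat), dimnames = dimnames(mat))
  chr[attr(mat, "zero_occurrence")] <- "NA:zero_occurrence"
  chr[attr(mat, "not_in_library")] <- "NA:not_in_library"
  df <- data.frame(amino_acid = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
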