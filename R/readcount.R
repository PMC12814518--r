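#' Extract the mutagenized window from one read
#'
#' Locates the design's upstream flank by exact match, checks that the
#' downstream flank follows at exactly `3 * n_positions` nucleotides, and
#' returns the enclosed window. If the upstream flank is absent on the
#' forward strand the reverse complement is scanned. No mismatches or
#' indels are tolerated: the window sits inside fixed amplicon context, so
#' reads with errors in the flanks are dropped rather than aligned.
#'
#' @param read_sequence an A/C/G/T/N string.
#' @param design a [library_design()].
#' @return the window string, or (invisibly typed as character) one of the
#'   rejection reasons `"flank_not_found"`, `"bad_spacing"`,
#'   `"n_in_window"` with attribute `rejected = TRUE`.
#' @export
extract_window <- function(read_sequence, design) {
  r <- extract_windows(read_sequence, design)
  if (!is.na(r$window)) return(r$window)
  structure(r$reason, rejected = TRUE)
}

## Vectorized extraction: returns list(window=, reason=) character vectors;
## window is NA where rejected.
extract_windows <- function(reads, design) {
  up <- design$flank_up; dn <- design$flank_down; w <- design$window_width
  window <- rep(NA_character_, length(reads))
  reason <- rep(NA_character_, length(reads))
  if (length(reads) == 0L) return(list(window = window, reason = reason))

  pos <- regexpr(up, reads, fixed = TRUE)
  miss <- pos < 0L
  if (any(miss)) {
    # reverse-complement rescue only when the forward strand lacks flank_up
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(gsub("[^ACGTN]", "N", reads[miss]))))
    rpos <- regexpr(up, rc, fixed = TRUE)
    reads[miss] <- rc
    pos[miss] <- rpos
  }
  found <- pos > 0L
  reason[!found] <- "flank_not_found"

  if (any(found)) {
    start <- pos[found] + nchar(up)
    win <- substr(reads[found], start, start + w - 1L)
    after <- substr(reads[found], start + w, start + w + nchar(dn) - 1L)
    ok_sp <- nchar(win) == w & after == dn
    idx <- which(found)
    reason[idx[!ok_sp]] <- "bad_spacing"
    hasN <- ok_sp & grepl("N", win, fixed = TRUE)
    reason[idx[hasN]] <- "n_in_window"
    good <- ok_sp & !hasN
    window[idx[good]] <- win[good]
  }
  list(window = window, reason = reason)
}

#' Count variants from per-passage FASTQ files
#'
#' For each passage file: extracts the mutagenized window from every read
#' ([extract_window()] policy), translates it with the standard code, and
#' collapses synonymous codon windows to protein variants. Reads that fail
#' extraction or translation are tallied by reason; accepted + rejected
#' equals the raw read count per passage, and the result is independent of
#' read order.
#'
#' @param files named character vector of FASTQ paths (plain or gzip);
#'   names are passage labels (`input`, `P1`, ...). Unnamed vectors get
#'   labels `input`, `P1`, `P2`, ...
#' @param design a [library_design()].
#' @param variants optional character vector fixing the row universe (e.g.
#'   [enumerate_protein_variants()]); defaults to the variants observed.
#' @return a [count_table()].
#' @export
count_fastq <- function(files, design, variants = NULL) {
  stopifnot(inherits(design, "library_design"), length(files) >= 1L)
  if (is.null(names(files)))
    names(files) <- c("input", paste0("P", seq_along(files)))[seq_along(files)]
  per_passage <- lapply(names(files), function(p) {
    path <- files[[p]]
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
      error = function(e) stop("cannot read FASTQ for passage '", p, "': ",
                               conditionMessage(e), call. = FALSE))
    ext <- extract_windows(unname(reads), design)
    prot <- translate_windows(ext$window, design)
    bad_tr <- !is.na(ext$window) & is.na(prot)
    ext$reason[bad_tr] <- "untranslatable"
    acc <- prot[!is.na(prot)]
    counts <- if (length(acc)) table(acc) else table(character(0))
    rej <- table(factor(ext$reason, levels = REJECT_REASONS))
    list(counts = counts, rejected = rej)
  })
  names(per_passage) <- names(files)
  all_vars <- variants
  if (is.null(all_vars))
    all_vars <- sort(unique(unlist(lapply(per_passage,
                                          function(x) names(x$counts)))))
  if (length(all_vars) == 0L) all_vars <- design$wildtype_protein
  counts <- matrix(0, length(all_vars), length(files),
                   dimnames = list(all_vars, names(files)))
  rejected <- matrix(0, length(REJECT_REASONS), length(files),
                     dimnames = list(REJECT_REASONS, names(files)))
  for (p in names(files)) {
    cp <- per_passage[[p]]$counts
    cp <- cp[names(cp) %in% all_vars]
    counts[names(cp), p] <- as.numeric(cp)
    rejected[, p] <- as.numeric(per_passage[[p]]$rejected)
  }
  count_table(design, counts, rejected = rejected)
}
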