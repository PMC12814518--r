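#' Describe a site-saturation library
#'
#' A `library_design` records everything needed to interpret a mutagenized
#' codon window: how many codons were randomized, which residue numbers they
#' correspond to, the wild-type protein sequence at those positions, and the
#' fixed nucleotide flanks bounding the window in the amplicon.
#'
#' The default design is the three-codon saturation of RbcL residues
#' 331/332/333 (wild type Asp-Arg-Ala, "DRA"). The flanks are synthetic
#' anchor sequences used by the simulator and the read counter; any fixed
#' A/C/G/T context of the real amplicon can be substituted.
#'
#' @param n_positions number of mutagenized codons.
#' @param position_labels residue numbers of the mutagenized positions.
#' @param wildtype_protein wild-type amino acids at those positions, as a
#'   single string of length `n_positions`.
#' @param flank_up,flank_down fixed nucleotide sequences immediately
#'   upstream/downstream of the mutagenized window.
#' @return an object of class `library_design`.
#' @examples
#' d <- library_design()
#' d$window_width   # 9 nt
#' @export
library_design <- function(n_positions = 3L,
                           position_labels = c(331L, 332L, 333L),
                           wildtype_protein = "DRA",
                           flank_up = "ACTGGTACCGTTCTGGCTAA",
                           flank_down = "GGTTCTACCCTGGGTCACCC") {
  n_positions <- as.integer(n_positions)
  stopifnot(n_positions >= 1L,
            length(position_labels) == n_positions,
            nchar(wildtype_protein) == n_positions)
  for (fl in c(flank_up, flank_down)) {
    if (!nzchar(fl) || grepl("[^ACGT]", fl))
      stop("flanks must be non-empty A/C/G/T strings", call. = FALSE)
  }
  if (!all(strsplit(wildtype_protein, "")[[1]] %in% AA_ALPHABET_20))
    stop("wildtype_protein must use standard one-letter amino acids",
         call. = FALSE)
  structure(list(
    n_positions = n_positions,
    position_labels = as.integer(position_labels),
    wildtype_protein = wildtype_protein,
    flank_up = flank_up,
    flank_down = flank_down,
    window_width = 3L * n_positions
  ), class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("Site-saturation library design\n")
  cat("  positions: ", paste(x$position_labels, collapse = "/"),
      "  (", x$n_positions, " codons, window ", x$window_width, " nt)\n",
      sep = "")
  cat("  wild type:", x$wildtype_protein, "\n")
  cat("  flanks:   ", x$flank_up, "[window]", x$flank_down, "\n")
  invisible(x)
}

## 20 standard amino acids; '*' marks a stop codon. Library members are
## identified by protein strings over this 21-letter alphabet.
AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_21 <- c(AA_ALPHABET_20, "*")

## Standard genetic code (E. coli host), codon -> one-letter aa, stop = '*'.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  ifelse(gc == "*", "*", as.character(gc))
}

#' Enumerate the protein-level variant space
#'
#' All protein sequences of length `n_positions` over the 21-letter alphabet
#' (20 amino acids plus the stop symbol `*`): a 3-codon saturation library
#' has 21^3 = 9261 protein-level members.
#'
#' @param design a [library_design()].
#' @return character vector of protein variant strings (e.g. `"DRA"`).
#' @examples
#' length(enumerate_protein_variants(library_design()))  # 9261
#' @export
enumerate_protein_variants <- function(design) {
  stopifnot(inherits(design, "library_design"))
  grids <- rep(list(AA_ALPHABET_21), design$n_positions)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

#' Translate a mutagenized codon window
#'
#' Translates a `3 * n_positions` nucleotide window with the standard genetic
#' code. Scalar interface: invalid input is an error. Batch counting uses
#' [translate_windows()] which flags invalid windows instead of failing.
#'
#' @param codon_seq nucleotide string of length `3 * n_positions`.
#' @param design a [library_design()].
#' @return list with `protein_seq` and `contains_stop`.
#' @examples
#' translate_window("GATCGCGCG", library_design())$protein_seq  # "DRA"
#' @export
translate_window <- function(codon_seq, design) {
  stopifnot(inherits(design, "library_design"))
  p <- translate_windows(codon_seq, design)
  if (is.na(p)) stop("invalid codon window: ", codon_seq, call. = FALSE)
  list(protein_seq = p, contains_stop = grepl("*", p, fixed = TRUE))
}

## Vectorized window translation; returns NA for windows of the wrong
## length or with non-ACGT characters (rejected-read signal, not an error).
translate_windows <- function(codon_seqs, design) {
  out <- rep(NA_character_, length(codon_seqs))
  ok <- !is.na(codon_seqs) &
    nchar(codon_seqs) == design$window_width &
    !grepl("[^ACGT]", codon_seqs)
  if (!any(ok)) return(out)
  tab <- codon_table()
  seqs <- codon_seqs[ok]
  n <- design$n_positions
  aa <- vapply(seq_len(n), function(i) {
    tab[substr(seqs, 3L * i - 2L, 3L * i)]
  }, character(length(seqs)))
  if (length(seqs) == 1L) aa <- matrix(aa, nrow = 1L)
  out[ok] <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
  out
}

#' Collapse codon-level counts to protein-level counts
#'
#' Sums counts over synonymous codon windows. Total counts are conserved
#' exactly; windows that fail translation are dropped with a warning (batch
#' FASTQ counting rejects them upstream, so this is a safety net).
#'
#' @param codon_counts named numeric vector, names are codon windows.
#' @param design a [library_design()].
#' @return named numeric vector keyed by protein variant string.
#' @export
collapse_to_protein <- function(codon_counts, design) {
  stopifnot(inherits(design, "library_design"))
  if (length(codon_counts) == 0L) return(stats::setNames(numeric(0), character(0)))
  prot <- translate_windows(names(codon_counts), design)
  if (anyNA(prot)) {
    warning(sum(is.na(prot)), " untranslatable codon window(s) dropped")
    codon_counts <- codon_counts[!is.na(prot)]
    prot <- prot[!is.na(prot)]
  }
  res <- rowsum(as.numeric(codon_counts), group = prot)
  stats::setNames(res[, 1L], rownames(res))
}

#' Pick one canonical codon per amino acid
#'
#' Used by the simulator to emit reads for protein-level variants: each amino
#' acid (and the stop symbol) is assigned its alphabetically first codon
#' under the standard code.
#'
#' @return named character vector, amino acid -> codon.
#' @export
canonical_codons <- function() {
  tab <- codon_table()
  ord <- order(names(tab))
  tab <- tab[ord]
  stats::setNames(names(tab)[!duplicated(tab)], tab[!duplicated(tab)])
}

## Reverse-translate a protein variant string using canonical codons.
reverse_translate <- function(protein_seqs, codons = canonical_codons()) {
  vapply(strsplit(protein_seqs, ""), function(aa)
    paste0(codons[aa], collapse = ""), character(1))
}

has_stop <- function(protein_seqs) grepl("*", protein_seqs, fixed = TRUE)
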