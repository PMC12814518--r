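#' Draw a ground-truth propagation landscape for a saturation library
#'
#' Builds per-variant propagation factors (expected phage offspring per
#' passage, wild type = 1) from an additive per-(amino acid, position)
#' penalty model:
#'
#'   rho(v) = 10^( -sum_p penalty(aa_p, p) )
#'
#' Penalties are drawn once per (amino acid, position) cell: with
#' probability `neutral_prob` a near-neutral penalty (uniform on
#' \[0, 0.15\] log10 units), otherwise a deleterious one
#' (0.3 + Gamma(shape 2, rate 1.5), mean ~1.6). The wild-type residue at
#' each position is anchored at penalty 0 and stop codons are lethal
#' (penalty 8 per stop). Under chaperonin (GroELS) overexpression missense
#' penalties are multiplied by `groels_buffer` (<= 1); stop penalties are
#' never buffered, since overexpressed chaperonin cannot rescue a
#' truncated chain.
#'
#' @param design a [library_design()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param groels_buffer multiplier in (0, 1] applied to missense log10
#'   deficits under +GroELS (1 = no rescue). Default 0.5.
#' @param neutral_prob fraction of (aa, position) cells that are
#'   near-neutral. Default 0.1.
#' @return an object of class `ground_truth`: list with `penalties`
#'   (21 x n_positions matrix), `rho_minus`, `rho_plus` (named vectors over
#'   all protein variants), `assembly_competent` (logical, rho_minus within
#'   ~3-fold of wild type), `groels_buffer`.
#' @export
ground_truth <- function(design, seed = 1L, groels_buffer = 0.5,
                         neutral_prob = 0.1) {
  stopifnot(inherits(design, "library_design"),
            groels_buffer > 0, groels_buffer <= 1)
  set.seed(seed)
  np <- design$n_positions
  pen <- matrix(0, nrow = 21L, ncol = np,
                dimnames = list(AA_ALPHABET_21, paste0("pos", seq_len(np))))
  wt <- strsplit(design$wildtype_protein, "")[[1]]
  for (p in seq_len(np)) {
    neutral <- stats::runif(20) < neutral_prob
    pen[1:20, p] <- ifelse(neutral,
                           stats::runif(20, 0, 0.15),
                           0.3 + stats::rgamma(20, shape = 2, rate = 1.5))
    pen[wt[p], p] <- 0
  }
  pen["*", ] <- STOP_PENALTY
  variants <- enumerate_protein_variants(design)
  rho_of <- function(buffer) {
    aa <- do.call(rbind, strsplit(variants, ""))
    tot <- numeric(length(variants))
    for (p in seq_len(np)) {
      pp <- pen[aa[, p], p]
      buffered <- ifelse(aa[, p] == "*", pp, pp * buffer)
      tot <- tot + buffered
    }
    stats::setNames(10^(-tot), variants)
  }
  rho_minus <- rho_of(1)
  rho_plus <- rho_of(groels_buffer)
  structure(list(
    penalties = pen,
    rho_minus = rho_minus,
    rho_plus = rho_plus,
    assembly_competent = rho_minus >= 10^(-0.5),
    groels_buffer = groels_buffer
  ), class = "ground_truth")
}

STOP_PENALTY <- 8

#' Parameters for a simulated serial-passage selection
#'
#' Bundles the generative model of one selection arm: per-variant
#' propagation factors, the infection bottleneck, sequencing depth, number
#' of passages, the pre-selection pool composition, and the hitchhiker
#' (second-site mutation) process.
#'
#' Defaults mirror the original selection conditions: 3 passages, a 1e5
#' phage infection bottleneck, and an input pool whose log-normal abundance
#' spread (sdlog 1.7) at 2e6 reads per passage leaves a realistic minority
#' of the 9261 library members under the 10-read detection threshold.
#'
#' @param design a [library_design()].
#' @param rho named positive vector of propagation factors (expected
#'   offspring multiplier per passage), one per variant in the pool.
#' @param n_passages number of selection passages. Default 3.
#' @param bottleneck phage drawn per infection (multinomial); `Inf` gives
#'   the deterministic expectation. Default 1e5.
#' @param read_depth sequencing reads per passage sample. Default 2e6.
#' @param input_abundance named nonnegative vector of pre-selection pool
#'   composition (unnormalized). Default: log-normal, sdlog 1.7, drawn from
#'   `seed` over `names(rho)`.
#' @param hitchhiker_rate probability per genome per passage of acquiring a
#'   second-site boost mutation. Default 0 (off).
#' @param hitchhiker_boost multiplier applied to a carrier's rho. Default 30.
#' @param seed integer seed for all randomness in [run_selection()].
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(design, rho, n_passages = 3L, bottleneck = 1e5,
                       read_depth = 2e6, input_abundance = NULL,
                       hitchhiker_rate = 0, hitchhiker_boost = 30,
                       seed = 1L) {
  stopifnot(inherits(design, "library_design"),
            !is.null(names(rho)), all(rho > 0),
            bottleneck >= 1, is.finite(read_depth), read_depth >= 1,
            n_passages >= 1,
            hitchhiker_rate >= 0, hitchhiker_rate <= 1,
            hitchhiker_boost > 0)
  if (is.null(input_abundance)) {
    set.seed(seed)
    input_abundance <- stats::setNames(
      stats::rlnorm(length(rho), meanlog = 0, sdlog = 1.7), names(rho))
  }
  stopifnot(!is.null(names(input_abundance)),
            all(names(input_abundance) %in% names(rho)),
            all(input_abundance >= 0), sum(input_abundance) > 0)
  structure(list(
    design = design, rho = rho, n_passages = as.integer(n_passages),
    bottleneck = bottleneck, read_depth = read_depth,
    input_abundance = input_abundance,
    hitchhiker_rate = hitchhiker_rate, hitchhiker_boost = hitchhiker_boost,
    seed = seed
  ), class = "sim_params")
}

#' Run one simulated selection arm
#'
#' Serial-passage model: passage 0 is the normalized input pool; each
#' passage (i) draws `bottleneck` phage multinomially from the current
#' frequencies, (ii) lets each drawn genome acquire a hitchhiker boost with
#' probability `hitchhiker_rate` (carriers persist across passages),
#' (iii) multiplies each genome class by its expected offspring rho and
#' renormalizes. Sequencing counts per passage are multinomial at
#' `read_depth`. With `bottleneck = Inf` every sampling step except
#' sequencing is replaced by its expectation. Fully reproducible from
#' `params$seed`.
#'
#' @param params a [sim_params()].
#' @return an object of class `selection_sim`: list with `freq`
#'   (variant x passage matrix of true pool frequencies, columns `input`,
#'   `P1`, ...), `titers` (input/output phage per passage; output =
#'   expected offspring of the bottlenecked pool), `table` (a
#'   [count_table()] of sequencing counts), `params`.
#' @export
run_selection <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  v <- names(params$rho)
  nv <- length(v)
  rho <- as.numeric(params$rho)
  ab <- stats::setNames(numeric(nv), v)
  ab[names(params$input_abundance)] <- params$input_abundance
  if (sum(ab) <= 0) stop("degenerate pool: all abundances zero", call. = FALSE)
  freq_plain <- ab / sum(ab)
  freq_hh <- numeric(nv)
  npass <- params$n_passages
  labels <- c("input", paste0("P", seq_len(npass)))
  freq <- matrix(0, nv, npass + 1L, dimnames = list(v, labels))
  counts <- matrix(0, nv, npass + 1L, dimnames = list(v, labels))
  titer_in <- titer_out <- stats::setNames(rep(NA_real_, npass),
                                           labels[-1L])
  seq_sample <- function(f) {
    as.numeric(stats::rmultinom(1L, params$read_depth, f))
  }
  freq[, 1L] <- freq_plain + freq_hh
  counts[, 1L] <- seq_sample(freq[, 1L])
  finite_bn <- is.finite(params$bottleneck)
  for (p in seq_len(npass)) {
    ftot <- c(freq_plain, freq_hh)
    if (sum(ftot) <= 0) stop("degenerate pool at passage ", p, call. = FALSE)
    if (finite_bn) {
      n <- as.numeric(stats::rmultinom(1L, params$bottleneck, ftot))
      n_plain <- n[seq_len(nv)]; n_hh <- n[nv + seq_len(nv)]
      if (params$hitchhiker_rate > 0) {
        moved <- stats::rbinom(nv, n_plain, params$hitchhiker_rate)
        n_plain <- n_plain - moved; n_hh <- n_hh + moved
      }
    } else {
      n_plain <- freq_plain; n_hh <- freq_hh
      if (params$hitchhiker_rate > 0) {
        moved <- n_plain * params$hitchhiker_rate
        n_plain <- n_plain - moved; n_hh <- n_hh + moved
      }
    }
    w_plain <- n_plain * rho
    w_hh <- n_hh * rho * params$hitchhiker_boost
    wsum <- sum(w_plain) + sum(w_hh)
    if (wsum <= 0) stop("degenerate pool at passage ", p, call. = FALSE)
    titer_in[p] <- if (finite_bn) params$bottleneck else 1
    titer_out[p] <- if (finite_bn) wsum else wsum / (sum(n_plain) + sum(n_hh))
    freq_plain <- w_plain / wsum
    freq_hh <- w_hh / wsum
    freq[, p + 1L] <- freq_plain + freq_hh
    counts[, p + 1L] <- seq_sample(freq[, p + 1L])
  }
  structure(list(
    freq = freq,
    titers = data.frame(passage = labels[-1L], input = titer_in,
                        output = titer_out,
                        fold_propagation = titer_out / titer_in,
                        row.names = NULL),
    table = count_table(params$design, counts),
    params = params
  ), class = "selection_sim")
}

#' @export
print.selection_sim <- function(x, ...) {
  cat("Simulated selection:", length(x$params$rho), "variants,",
      x$params$n_passages, "passages, bottleneck",
      format(x$params$bottleneck), "\n")
  cat("Fold propagation per passage:",
      paste(signif(x$titers$fold_propagation, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-variant takeover competition
#'
#' Competes the wild type (initial frequency `wt_fraction`, propagation
#' advantage `advantage`) against a single mutant, and records the majority
#' call per passage — a surrogate for genotyping the pool by Sanger
#' chromatogram, which reports the majority base at each position. A
#' 1-in-1001 wild-type minority with a >= 1000-fold advantage overtakes
#' the pool within three passages.
#'
#' @param wt_fraction initial wild-type frequency, in (0, 1).
#' @param advantage wild-type propagation factor relative to the mutant.
#' @param design a [library_design()] (labels only).
#' @param n_passages,bottleneck,read_depth,seed as in [sim_params()].
#' @return data.frame with passage, wt_freq, mut_freq, and `majority`
#'   ("WT" when the wild type strictly exceeds half the pool).
#' @export
simulate_competition <- function(wt_fraction, advantage,
                                 design = library_design(),
                                 n_passages = 3L, bottleneck = 1e5,
                                 read_depth = 1e5, seed = 1L) {
  stopifnot(wt_fraction > 0, wt_fraction < 1, advantage > 0)
  rho <- c(WT = advantage, MUT = 1)
  params <- sim_params(design, rho, n_passages = n_passages,
                       bottleneck = bottleneck, read_depth = read_depth,
                       input_abundance = c(WT = wt_fraction,
                                           MUT = 1 - wt_fraction),
                       seed = seed)
  sim <- run_selection(params)
  wt <- sim$freq["WT", ]
  data.frame(passage = colnames(sim$freq),
             wt_freq = as.numeric(wt),
             mut_freq = as.numeric(sim$freq["MUT", ]),
             majority = ifelse(wt > 0.5, "WT", "MUT"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate both selection arms from one input pool
#'
#' Runs the -GroELS and +GroELS arms of a selection on the same input
#' library: the input pool composition and its sequencing sample are drawn
#' once and shared, so the two arms are thresholded over an identical
#' variant set, as when one physical library is split across conditions.
#'
#' @param truth a [ground_truth()].
#' @param design a [library_design()].
#' @param seed integer seed.
#' @inheritParams sim_params
#' @return list with `minus` and `plus` (each a `selection_sim`) and
#'   `truth`.
#' @export
simulate_experiment <- function(design = library_design(),
                                truth = ground_truth(design),
                                n_passages = 3L, bottleneck = 1e5,
                                read_depth = 2e6,
                                hitchhiker_rate = 0, hitchhiker_boost = 30,
                                seed = 1L) {
  set.seed(seed)
  ab <- stats::setNames(
    stats::rlnorm(length(truth$rho_minus), 0, 1.7), names(truth$rho_minus))
  input_counts <- as.numeric(stats::rmultinom(1L, read_depth, ab / sum(ab)))
  arm_seeds <- sample.int(.Machine$integer.max, 2L)
  arm <- function(rho, s) {
    p <- sim_params(design, rho, n_passages = n_passages,
                    bottleneck = bottleneck, read_depth = read_depth,
                    input_abundance = ab, hitchhiker_rate = hitchhiker_rate,
                    hitchhiker_boost = hitchhiker_boost, seed = s)
    sim <- run_selection(p)
    sim$table$counts[, "input"] <- input_counts  # shared input sample
    sim$table <- count_table(design, sim$table$counts)
    sim
  }
  list(minus = arm(truth$rho_minus, arm_seeds[1L]),
       plus = arm(truth$rho_plus, arm_seeds[2L]),
       truth = truth)
}

#' Emit simulated sequencing reads as FASTQ
#'
#' Writes one FASTQ per passage whose composition equals the simulation's
#' sequencing count table exactly: each read is the design's upstream
#' flank, the variant's codon window (canonical codon per amino acid), and
#' the downstream flank, at uniform high quality. Exercises the FASTQ
#' counting path end-to-end against a known emission table.
#'
#' @param sim a `selection_sim` from [run_selection()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, one per passage.
#' @export
emit_fastq <- function(sim, dir) {
  stopifnot(inherits(sim, "selection_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- sim$params$design
  windows <- reverse_translate(rownames(sim$table$counts))
  paths <- character(0)
  for (p in sim$table$passages) {
    cnt <- sim$table$counts[, p]
    seqs <- rep(paste0(design$flank_up, windows, design$flank_down), cnt)
    qual <- strrep("I", nchar(design$flank_up) + design$window_width +
                     nchar(design$flank_down))
    path <- file.path(dir, paste0(p, ".fastq"))
    con <- file(path, "w")
    if (length(seqs) > 0) {
      writeLines(paste0("@", p, "_", seq_along(seqs), "\n", seqs,
                        "\n+\n", qual), con)
    }
    close(con)
    paths[p] <- path
  }
  paths
}
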