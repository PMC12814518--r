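# Shared fixtures: small designs and count tables built in code.

toy_design <- function(n = 3L) {
  library_design(
    n_positions = n,
    position_labels = seq(331L, length.out = n),
    wildtype_protein = substr("DRA", 1L, n)
  )
}

# A count table with hand-chosen input/P1 columns.
toy_table <- function(design = toy_design(),
                      input, final, label_final = "P1") {
  stopifnot(identical(names(input), names(final)))
  counts <- cbind(input = input, final)
  colnames(counts) <- c("input", label_final)
  count_table(design, counts)
}

# A small random propagation landscape over `nv` non-stop variants.
toy_rho <- function(design, nv = 50, seed = 1, spread = 2) {
  set.seed(seed)
  vars <- enumerate_protein_variants(design)
  vars <- vars[!grepl("*", vars, fixed = TRUE)]
  vars <- sample(vars, nv)
  stats::setNames(10^stats::runif(nv, -spread, 0), vars)
}
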