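---
title: "Methods: selection-sequencing analysis and the serial-passage simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-sequencing analysis and the serial-passage simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancseq)
```

## Overview

`pancseq` analyzes phage-assisted noncontinuous selections (PANCS) of
site-saturation mutagenesis libraries. In such an experiment a library of
protein variants — here the 3-codon saturation of RbcL residues
331/332/333, 21^3 = 9261 protein-level members including stop-containing
sequences — is carried on M13 phage whose propagation requires the variant
to pass a phenotypic gate (assembly competence). The pool is passaged
serially; each passage infects a culture with a fixed number of phage
(10^5, the infection bottleneck) and amplifies variants in proportion to
their propagation ability. Amplicon sequencing of the mutagenized window
before selection and after every passage yields a variant-by-passage count
table, from which the package computes frequency trajectories, fitness
scores, an assembly-outcome classification, and residue-level enrichment
maps.

Because the underlying sequencing data of the motivating experiment are
not deposited, the package pairs every analysis stage with a generative
simulator whose output has the same shape as the real data. The simulator
is first-class, tested code: it supplies ground truth for unit and
end-to-end tests, and its defaults encode the study conditions described
below.

## The fitness model

For a variant $v$ let $f_0(v)$ be its fraction of sequencing reads in the
input library and $f_T(v)$ its fraction in the final passage (both over
the variants retained by the detection threshold). The fitness score is

$$ w(v) = \log_{10}\frac{f_T(v)}{f_0(v)} $$

so $w = 0$ means unchanged relative abundance, $w = -1$ a tenfold
de-enrichment. Three modelling choices deserve comment:

* **No pseudocounts.** A variant with zero reads in the final passage gets
  no finite score; it forms an explicit *depleted* class. This mirrors the
  separate "completely depleted" accounting of selection experiments and
  avoids scores whose magnitude depends on an arbitrary prior count.
* **Input and final passage only.** Intermediate passages feed the
  trajectory output (and the `plot` method), not the score. With a single
  effective generation per passage the expected score is linear in the
  number of passages, so a per-passage slope estimator would change the
  scale but not the ranking; without replicate structure there is no basis
  for a more elaborate estimator.
* **Classification.** Retained variants are partitioned into `depleted`
  (zero final reads), `positive` ($w > 0$) and `negative`
  ($w \le 0$, detected). A variant is *predicted to have lowered assembly
  efficiency* when it is depleted or $w \le -1.0$; the bound is inclusive
  and tunable (`lowered_bound`). No third "uncertain" band is added around
  zero: near-zero scores are known not to predict assembly reliably in
  either direction, and the boolean encodes the only rule that is
  defensible from the selection itself.

The detection threshold (`min_input_reads`, default 10) is applied to the
input library only. Variants below it never enter the analysis; variants
above it that vanish later are what the depleted class captures.

## The enrichment matrix

For the positive set $P$ (positive-fitness variants, by default
intersected across selection arms, stop-containing sequences excluded) and
the starting set $S$ (all retained variants), the enrichment score of
amino acid $a$ at position $p$ is

$$ E(a,p) = \log_{10}\frac{\#\{a \text{ at } p \text{ in } P\}}{\#\{a \text{ at } p \text{ in } S\}} $$

with a pooled `total` column in which a variant contributes one occurrence
per position-slot. Because $P \subseteq S$, every defined cell of this
literal count ratio is $\le 0$; a cell is the zero-occurrence
("crossed-out") sentinel when the amino acid never occurs in $P$ at that
position, and marked not-in-library when it is absent even from $S$.
An optional *centered* mode subtracts $\log_{10}(|P|/|S|)$ (on occurrence
totals) so that 0 means "survived selection at the average rate" and
favored residues become positive — usually the more readable heat map. The
output labels which mode was used; the literal mode is the default.

## The serial-passage simulator

`run_selection()` implements a discrete generative model. Passage 0 is the
normalized input pool. Each passage:

1. draws `bottleneck` phage multinomially from the current pool
   frequencies (the 10^5-phage infection bottleneck);
2. lets every drawn genome acquire a *hitchhiker* second-site mutation
   with probability `hitchhiker_rate`; carriers keep a `hitchhiker_boost`
   multiplier on their propagation factor for all later passages (the
   carrier state is tracked per variant as a second compartment — the
   hitchhiker's own sequence is not modelled);
3. multiplies each genome class by its propagation factor $\rho(v)$
   (expected offspring per phage per passage, one effective generation per
   passage) and renormalizes.

Sequencing counts for every passage are an independent multinomial draw of
`read_depth` reads from the pool frequencies. `bottleneck = Inf` replaces
every sampling step except sequencing with its expectation, giving the
deterministic limit used by the closed-form tests (two-variant odds after
$p$ passages equal initial odds times $a^p$ for a propagation ratio $a$).
All randomness flows through one seed; identical parameters and seed give
bit-identical count tables.

A uniform hitchhiker rate multiplies every lineage by the same expected
factor and therefore cancels from deterministic relative frequencies; its
effect is stochastic — rare acquisitions inflate particular carrier
lineages, which is exactly how spontaneous second-site mutations distort
real selections. The default rate is 0 so that core analyses are clean.

### Ground-truth landscape

`ground_truth()` draws an additive per-(amino acid, position) penalty
landscape: $\rho(v) = 10^{-\sum_p \mathrm{pen}(a_p, p)}$ with the wild-type
residue anchored at 0. Each of the 60 missense cells is near-neutral
(uniform on $[0, 0.15]$ log10 units) with probability 0.1 and deleterious
($0.3 + \Gamma(\text{shape}=2, \text{rate}=1.5)$, mean ≈ 1.6 log10 units)
otherwise; stops carry penalty 8 per stop codon. Under chaperonin
(GroELS) overexpression missense penalties are multiplied by
`groels_buffer` (default 0.5, i.e. the chaperonin halves every folding
deficit); stop penalties are never buffered, because overexpressed
chaperonin cannot rescue a truncated chain. The additive form is the
simplest landscape that reproduces the qualitative structure of the real
selection — a minority of tolerated substitutions, strong depletion of
most variants, position-specific residue preferences, and a
chaperonin-dependent rescue — and it makes the buffer's effect on every
variant analytically checkable. It deliberately omits epistasis between
the three positions.

### Default study conditions

The generator's defaults are the conditions of the experiment it
emulates, chosen once:

| parameter | default | why |
|---|---|---|
| `n_passages` | 3 | three selection passages |
| `bottleneck` | 1e5 | phage used to infect each culture |
| `read_depth` | 2e6 | with the abundance spread below, ~18% of the 9261 variants fall under the 10-read threshold, matching the reported scale of detection (7547/9261) |
| input abundance | log-normal, sdlog 1.7 | cloning yields strongly uneven libraries; this spread produces the detected fraction above at 2e6 reads |
| `groels_buffer` | 0.5 | halving of log-deficits reproduces a several-fold increase in surviving variants, the qualitative chaperonin effect |
| `hitchhiker_rate` | 0 | off unless studied explicitly |
| `hitchhiker_boost` | 30 | a boost large enough to mask a typical deficit, as observed for spontaneous second-site rescues |

The headline fractions of the motivating experiment (about 5.8% positive
without chaperonin, doubling with it, ~90% predicted lowered assembly) are
*qualitative shape targets* for these defaults, not calibrated outputs:
the simulated library reproduces their ordering and rough magnitude (a
small positive minority, chaperonin multiplying it severalfold, ~90+% of
variants predicted impaired) but not the exact values, which depend on
unknowable details of the real landscape.

### What the simulator does not emulate

Sequencing errors inside reads (reads are emitted error-free; the counting
module's rejection paths are exercised with constructed fixtures instead);
PCR amplification bias and duplicate reads; within-passage infection
kinetics and phage dose-response; codon-level library composition (the
simulator works at protein level and emits one canonical codon per amino
acid — synonymous-collapse behavior is tested with separate codon-level
fixtures); epistasis. Passing tests therefore demonstrate the correctness
of the analysis pipeline on data of realistic shape, not the fidelity of
any biological parameter.

## Read counting choices

The mutagenized window is located by exact match of both fixed flanks at
the expected spacing; a read is rejected (and tallied by reason:
`flank_not_found`, `bad_spacing`, `n_in_window`, `untranslatable`) rather
than error-corrected. The window is 9 nt inside fixed amplicon context, so
flank errors are rare events best absorbed as rejections, and the 10-read
detection threshold suppresses spurious variants created by errors inside
the window. The reverse complement is scanned only when the upstream flank
is absent on the forward strand. Base qualities are ignored: an `N` inside
the window is the only quality-based rejection. A mismatch-tolerant or
indel-aware mode is deliberately out of scope.

## Numerical and degenerate-input policy

Frequency vectors are renormalized each passage and checked to sum to 1
within 1e-9. A pool whose abundances are all zero, a zero-total passage
column, a missing input passage, an empty record set, and mismatched arm
variant sets are explicit errors, never silent results. Fitness for
`f_final = 0` is `NA` (depleted), never `-Inf`. Ties at exactly 0.5 in the
two-variant competition are not a majority: the takeover call requires a
strict majority, so a deterministic odds ratio of exactly 1 leaves the
incumbent called.

## Problem sizes used by the test suite

Tests run the full 9261-variant library where the quantity under test
needs it (ground-truth invariants, detection census, the two-arm
experiment at 2e5–5e5 reads per passage, 100-seed property checks) and
smaller pools (5–500 variants, 1e4–1e6 reads) for closed-form and
recovery checks; these sizes are the package's own choice of desk-scale
defaults for reproducible examples. The fitness-recovery check uses 500
variants at 1e6 reads and requires Spearman correlation ≥ 0.8 between
true log10 propagation factors and estimated fitness among variants with
defined scores; in practice it exceeds 0.95.

## Known limitations

Fitness scores are relative to the pool composition: the same variant in a
different library gets a different score, and scores from arms with
different compositions are not directly comparable (the arm comparison
therefore insists on a shared retained set). Low selection stringency
compresses the dynamic range near the top — positive fitness indicates
some assembly, not wild-type-level assembly. Hitchhiker mutations inflate
carrier variants' scores; the simulator can generate this failure mode,
but the analysis cannot detect it from window sequencing alone (that
requires full-length sequencing of the selected pool).
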