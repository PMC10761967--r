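---
title: "Screening ortholog groups for lineage-specific divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ortholog groups for lineage-specific divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscreen)
```

# The problem

When a lineage loses or remodels a conserved structure — the motivating case
is the degeneration of the sperm centriole in murid rodents — the proteins
that build that structure are released from some of their usual constraint
and may diverge unusually fast in exactly that lineage. `orthoscreen`
implements a deliberately simple, desk-scale screen for such proteins. It
needs nothing but one representative protein sequence per species per gene:
no codon-model fitting, no tree inference, no genome alignments.

The screen asks, gene by gene: *has the focal lineage diverged from a shared
reference more than a baseline lineage has?*

# The statistics and their assumptions

## Percent identity

All identities come from global (Needleman–Wunsch) alignment with affine gap
penalties, scored with BLOSUM62 at gap open 11 / extend 1 — the classical
protein-BLAST parameterization. Identity is reported as identical aligned
columns divided by **total alignment columns, gaps included**, ×100. That
denominator is the BLAST reporting convention, but it is not the only one in
use, and the original screen's alignment tool settings are not fully
specified; `percent_identity()` and everything downstream therefore accept
`denominator = "shorter"` (identities over the shorter sequence length) so
the sensitivity of any result to this choice can be reported directly.

Global rather than local alignment is a deliberate choice: the ratio
statistics below compare *whole-protein* divergence, and a local alignment
would silently discard the very regions (isoform-specific exons, fast
C-termini) the screen is most interested in.

The ambiguity letter `X` scores 0 against every residue and never counts as
an identity. Alignment tracebacks are deterministic; where several
alignments share the optimal score the reported identity count is that of
the deterministic traceback, and the tested invariant is score optimality
(checked against an independent dynamic program and exhaustive enumeration),
not a particular tie-breaking path.

## Identity Ratio and Extended Identity Ratio

With roles *reference* (default `human`), *focal* (`house_mouse`) and
*baseline* (`bovine`):

$$\mathrm{IR} = \frac{\mathrm{pid}(\text{ref}, \text{focal})}
                    {\mathrm{pid}(\text{ref}, \text{base})}$$

If the focal species is phylogenetically closer to the reference than the
baseline is, a clock-like gene has IR > 1. IR < 1 therefore means the focal
lineage has diverged *more* than its phylogenetic position predicts — the
signature the screen looks for. The Extended Identity Ratio strengthens this
by averaging over a reference trio (default `human`, `bovine`, `rabbit`):

$$\mathrm{EIR} = \frac{\sum_{i} \mathrm{pid}(\text{focal}, t_i)}
                      {\sum_{i<j} \mathrm{pid}(t_i, t_j)}$$

Both ratios are invariant to uniform rescaling of the identity matrix and
the EIR denominator is a symmetric sum, so trio order is irrelevant. Ratios
are computed at full precision and rounded to two decimals only in reports.

Neither statistic is a formal rate test: there is no correction for
phylogenetic non-independence, among-site rate variation, or alignment
uncertainty. The screen is a *ranking* device whose hits deserve proper
codon-model follow-up; that is also why the companion ω estimator below is a
counting method, not a likelihood model.

## Outlier fencing

A screened gene set yields a ratio distribution summarized by its median and
quartiles, with quartiles computed by linear interpolation between order
statistics (`stats::quantile` type 7, the most common convention — fixed so
that stored expectations remain stable). Genes below the Tukey lower fence

$$\text{fence} = Q_1 - 1.5\,\mathrm{IQR}$$

are flagged. The fence needs at least four finite ratios; below that
`tukey_summary()` refuses rather than returning something meaningless. On
equal-rate simulated screens the flag rate at this fence is small (under 5%
of genes), so a flagged gene carries real signal rather than tail noise.

## Exon-partition selection rates

Externally produced selected-site calls (MEME/FEL/FUBAR-class analyses; this
package consumes their positions and classes, it never re-runs them) are
assigned to exon partitions by 1-based inclusive residue intervals. Rates
are `100 × count / partition length`, reported to one decimal. Calls
spanning methods are never merged: `method` is a grouping key, and
duplicated `(position, class, method)` rows are rejected at parse time.
Positions covered by no partition are tallied separately so that counts are
conserved.

Two partitions are compared with the pooled two-proportion z-test

$$z = \frac{\hat p_1 - \hat p_2}
           {\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
  \qquad \hat p = \frac{x_1+x_2}{n_1+n_2}$$

with a two-tailed normal p-value and no continuity correction — the form
used by the common online "two population proportions" calculators, which
makes published p-values directly comparable. Degenerate pooled proportions
(0 or 1) are an error, not a silent zero.

```{r ztest}
two_proportion_z(38, 575, 1, 125)
```

## Counting-method ω (dN/dS)

`ng86_dnds()` implements the Nei–Gojobori (1986) counting estimator on
gap-free, stop-free pairwise codon alignments (standard genetic code):

* per-codon synonymous site fractions from the 9 single-nucleotide
  neighbors, with neighbors that are stop codons counted as nonsynonymous;
  each codon contributes exactly 3 sites, and sites are averaged over the
  two sequences;
* observed differences averaged over all minimal mutational paths between
  differing codons, **excluding paths that pass through a stop codon** (the
  standard NG86 choice); in the degenerate case where every path crosses a
  stop, all paths are used and the result is flagged;
* multiple-hit correction by the Jukes–Cantor transform
  $d = -\tfrac34\ln(1-\tfrac43 p)$, applied to both proportions;
* $\omega = d_N/d_S$, reported as undefined — with an explanatory flag,
  never as 0 — when $d_S = 0$ or when a proportion reaches the
  Jukes–Cantor saturation limit $p \ge 3/4$.

This is a deliberate stand-in for maximum-likelihood codon models (CodeML
M0 and relatives): counting methods are transparent, dependency-free and
adequate for calibration and ranking at desk scale, but they ignore
transition/transversion bias and codon frequencies, and their absolute ω
values are not comparable to published ML estimates, which additionally
depend on taxon sampling and tool versions. Nothing in this package asserts
equality with any published ω value.

## Predicted protein mass

`protein_mass()` uses average (isotope-abundance-weighted) residue masses
plus one water — the convention behind "predicted molecular weight" values —
via `seqinr::pmw`, divided by 1000 and conventionally rounded to the nearest
kDa for display. `X` is rejected because its mass is undefined.

# The synthetic-data generator

## Protein model

The simulator's purpose is *validation with known truth*, so the protein
model is chosen for analytic tractability rather than realism: along a
branch of effective length $d$ (branch length × per-branch multiplier), each
site receives $\mathrm{Poisson}(d)$ substitution events, each replacing the
residue uniformly among the other 19. Two leaves separated by total path
length $d$ then have expected identity

$$P(\text{identical}) = \tfrac1{20} + \tfrac{19}{20}\,e^{-20d/19},$$

which the tests use as an exact oracle. What this model does **not**
emulate: empirical exchangeabilities (a BLOSUM-like process), among-site
rate variation, indels, or domain structure. Passing recovery tests
therefore show that the *statistics* behave as designed on cleanly
accelerated data — they do not show that real proteomes are as well-behaved,
and real screens should expect heavier tails.

## Default species tree

```{r tree}
ape::write.tree(default_species_tree())
```

The topology is the Glires arrangement the screen's logic relies on: house
mouse groups with rabbit, then human, with bovine as outgroup. Branch
lengths are a design choice, not an estimate: they are set so the
human-to-mouse path (0.20 expected substitutions/site) is shorter than
human-to-bovine (0.22). That ordering is what makes the equal-rate
expectation IR > 1 hold — it encodes "humans should be more identical to
house mice than to bovine" — and only a focal-branch acceleration can push
simulated genes below 1. (A superficially similar parameterization with a
longer mouse terminal branch would *build the acceleration into the null*,
inverting the expectation; the package deliberately keeps the null clock-like
and injects acceleration only through explicit multipliers.)

## Codon model

Codon sites draw an ω class once at the root (classes and proportions are
user-specified); along each branch, nucleotide proposals arrive as a Poisson
process with transition/transversion bias κ; proposals creating stops are
rejected, and nonsynonymous proposals are accepted with probability
$\min(1, \omega)$. Default κ = 1: the NG86 estimator itself assumes
unbiased substitution, so the neutral calibration (mean estimated ω within
[0.9, 1.1] at true ω = 1) is a property of the estimator under its own model
assumptions; κ is exposed precisely so users can study how transition bias
distorts counting estimates. A small downward bias (a few percent) remains
even at κ = 1 because stop-neighbor changes are counted as nonsynonymous
sites but never realized by the stop-rejecting process; the calibration band
absorbs this.

# Numerical and interface choices

* **Coordinates** are 1-based inclusive everywhere, matching amino-acid
  numbering conventions.
* **Isoform selection**: the longest sequence per (gene, species); ties go
  to the lexicographically smallest accession, for determinism.
* **Gene symbols** are uppercased for matching; no alias or identifier
  mapping is attempted, so lists from different sources must already share a
  symbol namespace.
* **FASTA headers** default to `accession|gene_symbol|species`; plain
  accession headers are supported through a sidecar metadata TSV. Readers
  reject malformed rows with the offending record named, and warn (not
  error) on undeclared TSV columns.
* **Empty sequences** align as all-gap alignments; percent identity of a
  zero-length alignment is an error, not 0 or 100.
* **Seeds** are explicit in every stochastic function, and
  `generate_screen_dataset()` writes a manifest (tree, parameters, seed)
  beside its output, so any dataset can be regenerated byte-identically.
* The command-line interface is a thin layer over the same functions
  (`run_cli()` takes an argument vector and returns an exit status), so CLI
  results are identical to library calls by construction, and tested to be.

# Validation summary

The test suite validates each stage against an independent oracle: alignment
scores against a hand-written affine-gap DP and exhaustive enumeration on
short pairs; quartiles and fences against a manual sort-and-interpolate;
NG86 against frozen values from an independent implementation of the
counting rules on a fixture whose mutational paths avoid stop codons (so
path-handling conventions cannot differ); and the simulator against its own
closed form. End-to-end, a 200-gene screen with 20% of genes accelerated 2×
on the focal branch (300-aa proteins, 20 seeded replicates) ranks the
accelerated genes' median EIR below the background median in every
replicate, and 100 neutral 500-codon pairs calibrate the ω estimator to a
mean within [0.9, 1.1]. These problem sizes are the package's standard
validation conditions and run in well under a minute each on a laptop-class
machine.

# Known limitations

* The ratio statistics are screening heuristics, not phylogenetically
  corrected rate tests; hits need codon-model confirmation.
* The counting ω estimator ignores κ and codon frequencies and saturates
  near $p = 3/4$; it is not a substitute for ML estimates on deep
  divergences.
* The simulator omits indels and empirical substitution preferences, so it
  cannot probe alignment-driven artifacts.
* Reproducing identity values for specific published accessions depends on
  the exact database records and alignment settings used at the time; the
  identity-denominator option exists to make that sensitivity visible.
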