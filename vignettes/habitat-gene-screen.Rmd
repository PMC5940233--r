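---
title: "Screening plastid gene content for habitat association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plastid gene content for habitat association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastome)
```

# The problem

Red algal plastid genomes are unusually conserved in gene content, which
makes the exceptions informative. When a gene is systematically present
in marine species and absent in freshwater species (or the reverse)
across a survey of annotated plastomes, that pattern is a candidate
signature of environmental adaptation — the canonical example being the
plastid heme-oxygenase gene *pbsA*, retained where iron is scarce
(seawater) and dispensable where it is not (freshwater). This package
implements the complete desk workflow around that question: building
comparable gene inventories from heterogeneous GenBank records, screening
every gene for habitat association, asking whether losses track the
phylogeny, classifying the heme-oxygenase gene family by protein
architecture, and checking family boundaries with a similarity network.

# The screen

For each gene the species of the survey are cross-tabulated by habitat
(rows: marine, freshwater) and presence (columns: present, absent). Two
statistics are reported per gene.

**Concordance rate.** The fraction of species matching a habitat-specific
pattern: `(marine_present + freshwater_absent) / n` for the
marine-retained pattern, and its complement for the freshwater-retained
pattern. The larger of the two is reported with its direction, so the
rate is always ≥ 0.5; exact ties (rate 0.5) break toward
`marine_retained` for determinism. This is a descriptive effect size, not
a test.

**Chi-square test.** Pearson's statistic on the 2×2 table with df = 1 and
an upper-tail p-value, optionally with the Yates continuity correction.
Significance is declared at `alpha = 0.01` on the raw p-values — the
survey convention this package reproduces — with Bonferroni and
Benjamini–Hochberg adjustments available behind a flag for users who want
them. The statistic is implemented directly (and is cross-checked against
`stats::chisq.test` and an exact permutation oracle in the test suite);
both the uncorrected and corrected forms are exposed because published
surveys rarely state which was used.

Degenerate tables — a zero row or column margin, as for a gene present in
every species — have no defined statistic. They are returned flagged with
`chi2 = 0, p = 1` rather than raising, so a genome-wide screen never
aborts on an invariant gene. One deliberate edge: `alpha = 1` disables
the cutoff entirely and flags every gene, including the degenerate ones
that carry p = 1 (a strict `p < 1` would silently exclude exactly those).

**Brackish species** do not fit a two-habitat table. The default policy
excludes them (their count is recorded in the result), with explicit
`as_marine` / `as_freshwater` alternatives. This is surfaced as a
parameter rather than a buried convention because published survey
denominators are frequently irreconcilable with the stated composition —
in the motivating survey the printed marine denominator (116) equals
marine + brackish (109 + 2) under no policy, and the printed pbsA
concordance (84.1%) differs from the value its own printed marginals give
(112/132 = 84.8%). The package reports what the data yield under a named
policy and does not attempt to reverse-engineer the discrepancy.

# Parsimony mapping

Gene presence/absence is mapped on a rooted phylogeny by Fitch small
parsimony, implemented as unit-cost Sankoff dynamic programming so
multifurcating nodes are handled exactly. Branch lengths are ignored: the
mapping is qualitative. The minimum change count is unique; the internal
labeling is not, so the package makes its tie-breaks explicit:

* on the top-down pass an internal node that ties keeps its parent's
  state (changes are delayed toward the tips, ACCTRAN-like);
* a tie at the root resolves toward `present` by default — plastid genes
  are ancestrally encoded, so the natural reading of a change is a loss.

`count_losses_gains()` classifies each change on the resolved labeling as
a loss (present → absent) or gain (absent → present); the counts always
sum to the parsimony minimum, which the test suite enforces alongside
equality with brute-force enumeration on all trees up to 8 tips. The
`root_state_assumption = "present"` default asserts polarity only where
the optimum allows it: if the data force an absent root, forcing present
would break the minimality invariant, so the optimum wins.

Newick input is treated as rooted as written — the outermost clause is
the root, and a basal trifurcation is accepted as a multifurcating root.
The package never re-roots a tree, because loss/gain polarity depends
entirely on the root the user supplies.

# Protein architecture and isotype rules

The three heme-oxygenase isotypes differ by architecture, not by domain:
HMOX1 carries an N-terminal plastid-targeting transit peptide and no
transmembrane segment; HMOX2 is nuclear with a C-terminal (sometimes also
internal) transmembrane segment; pbsA is plastid-encoded with a
C-terminal transmembrane segment and no transit peptide. The original
survey used TargetP/ChloroP/TMHMM; those tools are not re-implemented.
Instead the package provides transparent stand-ins with every parameter
exposed, and accepts precomputed external calls through a TSV sidecar so
real-data runs can use the original predictors.

* **Transmembrane segments**: mean Kyte–Doolittle hydropathy in a
  sliding window (default width 19 residues, the classic choice),
  maximal runs above 1.6, runs closer than 3 residues merged, merged
  runs shorter than 15 residues discarded. A segment is C-terminal if it
  ends within the last 60 residues (the terminal-box width of the
  published architecture diagrams).
* **Transit peptide**: over the first 40 residues,
  `(S+T fraction) − (D+E fraction)` plus 0.1 for alanine at position 2,
  called at ≥ 0.15. Chloroplast transit peptides are S/T-rich,
  acid-depleted and usually start Met-Ala; the cutoff admits the obvious
  cases and is deliberately simple. Sequences under 40 residues are
  called negative with a flag.
* **Domain scan**: a log-odds position-weight matrix built from a
  packaged 60-column toy alignment (`hemeo_domain_synthetic.fasta` — a
  constructed stand-in, not curated biological data). The best ungapped
  placement is reported when its score reaches a cutoff calibrated at
  build time as mean + 3 SD of null scores under a fixed seed. The null
  uses the *same statistic as detection* — the best placement over all
  offsets, on shuffled triple-length copies of the alignment sequences.
  A single-placement null on the bare 60-mers puts the cutoff near 2
  bits, which the maximum over ~100 placements of a realistic query
  exceeds by chance (a planted poly-Leu segment alone scores ≈ 2.2); the
  placement-matched null puts it near 13 bits, leaving two orders of
  magnitude of margin to true domain scores (≈ 160 bits).

Classification is a pure function of the features, in priority order:
no detected domain → `unclassified`; transit and no TM → `HMOX1`;
C-terminal TM *and* transit → `pbsA` with a conflict note (the
architecture of a plastid-type gene retargeted from the nucleus, as in
*Cyanophora paradoxa* — the spec-level rules would otherwise leave this
biologically interpretable case unclassified); plastid-encoded with
C-terminal TM → `pbsA`; nucleus-encoded with C-terminal TM → `HMOX2`;
otherwise `unclassified` with the evidence that blocked.

# Similarity network

Hits in BLAST tabular layout become edges when e-value ≤ 1e-05, identity
≥ 20%, and the alignment covers ≥ 20% of the shorter sequence *and* ≥ 70%
of both sequences — the stated EGN settings applied conjunctively, which
makes the 20% clause redundant but keeps the filter verbatim. Coverage is
computed from the alignment-length column without subtracting gaps, and
per hit row (per HSP), both documented conventions. Self-hits are
dropped, reciprocal duplicates collapse to the lowest e-value, and the
node universe is the full lengths table so unconnected sequences appear
as singletons. The filter is idempotent and monotone in every threshold;
both properties are under test.

# What the generator emulates — and what it does not

The synthetic world's defaults are the stated survey conditions: 127
species (109 marine, 16 freshwater, 2 brackish); four habitat-linked
genes losing at 0.14 in marine and 0.75 in freshwater species (the
printed pbsA absence fractions, 16/116 and 12/16); 30 background core
genes at a uniform 0.02 loss. Where the survey stated no value, a choice
was made once: the null loss probability for error-rate characterization
is 0.5 (the maximum-variance null, most demanding of the chi-square
approximation), Yule birth rate 1, habitat transition rate 0.3 per unit
length (a few transitions per tree, echoing the handful of independent
freshwater colonizations in the real phylogeny).

Two loss regimes exist because the screen's calibration needs both: the
default star tree with per-tip losses gives the independence the
chi-square test assumes (this is the regime behind the type-I and power
properties: significant fraction inside the 95% binomial band around
alpha on 2000 null genes; ≥ 80% of planted 0.05/0.9 effects recovered
over 200 replicates at 20 + 16 tips); the Yule tree with branchwise
irreversible loss produces the clade-clustered absences a painted
phylogeny shows. The generator does **not** emulate phylogenetic
non-independence *within* the star-tree tests, annotation error
(a gene unannotated in a real record counts as absent — the screen
cannot distinguish loss from missed annotation), sequence evolution
(emitted GenBank records are structural fixtures with composition, not
homology), or correlated loss between genes. A green test therefore
establishes that the machinery is correct under the stated model, not
that the chi-square screen is robust to phylogenetic pseudo-replication —
the known limitation the parsimony mapping addresses descriptively, and
a phylogenetically corrected test (e.g. Pagel's) deliberately does not
enter scope.

# Numerical and format conventions

* Internal coordinates are 0-based half-open; GenBank's 1-based inclusive
  intervals convert at the I/O boundary only. Joined/trans-spliced
  locations collapse to one feature spanning their parts — only
  presence matters downstream.
* GC% is `100·(G+C)/(A+C+G+T)` ignoring ambiguity codes, rounded to one
  decimal, matching genome-table convention.
* Gene identity comes from the `gene` qualifier with a product-qualifier
  synonym fallback; normalization (case folding, `ycf` zero-pad removal,
  locus-suffix stripping, synonym lookup) is idempotent, and unknown
  names fall back to lower case so they remain fixed points.
* All generator randomness derives from one integer seed, consumed
  through an RNG-state-preserving wrapper, so package internals never
  disturb the caller's random stream and bundles are byte-identical
  under a fixed seed.

# Known limitations

Presence/absence is binary (copy number ignored); annotation quality
bounds inventory quality; the transit-peptide and transmembrane
heuristics are composition stand-ins, not the published predictors —
for real analyses supply external TargetP/ChloroP/TMHMM calls via the
sidecar; the printed survey percentages that depend on the supplementary
survey table cannot be recomputed from the package's inputs alone, and
the package makes no attempt to force agreement where the published
numbers are internally inconsistent.
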