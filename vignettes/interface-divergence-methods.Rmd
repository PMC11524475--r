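---
title: "Profiling clade divergence of helper NLR dimerization interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling clade divergence of helper NLR dimerization interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrcdiverge)
```

## The scientific problem

Helper NLR immune receptors of the NRC family form resting-state
homodimers, and the residues at the dimerization interface decide which
paralogs can associate with which. If paralogous helpers accumulate
clade-specific substitutions at that interface, the signalling nodes of
the immune network become *insulated* from one another: each clade
self-associates but no longer hetero-associates. `nrcdiverge` implements
the two computational legs of that argument:

1. **Sequence leg** — given a large, clade-partitioned alignment of NRC
   helpers, quantify per-position conservation (Shannon entropy) within
   each clade and across the family, and identify positions carrying a
   *clade-unique residue* using a relative amino-acid-ratio statistic.
2. **Structure leg** — given the coordinates of a two-protomer homodimer,
   extract the interface: inter-chain contact residues at a distance
   cutoff, their grouping into named stretches by partner-domain class,
   and the buried surface area (BSA) of each protomer.

A synthetic-data module generates clade-structured families with planted
diagnostic polymorphisms and toy two-chain structures with known
contacts, so that every stage can be validated against a known ground
truth without downloading anything.

## Column statistics and their conventions

All column statistics operate on the 20-letter amino-acid alphabet.
Gap characters (`-`) and ambiguity codes (`X`) are excluded from both
the numerator and the denominator of every frequency
(`column_frequencies()`), so a column's effective sample size
`n_effective` is the number of unambiguous residues among the subset
rows. A column that is entirely gaps within a subset is flagged rather
than given frequencies. The single gap character is `-`; `.` is
normalized to `-` on input. This gap-exclusive convention keeps the 80%
frequency rule (below) independent of how gappy a column is; the
alternative (gap-inclusive denominators) would silently shrink
frequencies at ragged alignment regions.

### Shannon entropy

`shannon_entropy()` is the plug-in estimator `H = -Σ p log2 p` over the
positive frequencies. It ranges from 0 bits at an invariant position to
`log2(20) ≈ 4.32` bits when all 20 amino acids are equally frequent. No
small-sample bias correction is applied: the quoted bounds are plug-in
values, and at the clade sizes this package targets (tens to low
hundreds of sequences) the correction is second-order compared to the
1.5-bit classification threshold. `entropy_profile()` classifies a
position as `variable` only when H **strictly exceeds** the threshold
(default 1.5 bits, the conventional cutoff for highlighting highly
variable NLR positions), so H = 1.5 exactly is `conserved`.

### The relative amino-acid ratio

For a query clade against the pooled remaining clades
(`relative_aa_ratio()`, `call_unique_residues()`,
`iterate_unique_calls()`):

* A position is **callable** only if the query clade's majority amino
  acid has frequency strictly above the frequency cutoff (default 0.8).
  At any cutoff above 0.5 at most one amino acid can qualify, so
  "one of the frequencies is more than 80%" is unambiguous in effect.
* The **ratio** is the query frequency of that amino acid divided by its
  frequency in the pooled subject group. Subjects are pooled across
  sequences (one frequency vector), not averaged per clade: the
  statistic compares a query group to a subject group.
* The position is a **unique residue** when the ratio strictly exceeds
  the ratio cutoff (default 50) or is infinite.
* If the amino acid is absent from the subject group the ratio is
  **infinite** — reported as a distinct `INF` token in output files,
  never as a large sentinel number, so downstream thresholds stay
  honest. A subject column that is all gaps also counts as absence.
* If every query sequence has a gap at the position the result is
  **`NA`**; positions where no amino acid clears the frequency cutoff
  are recorded as `below_cutoff`, which is distinct from `NA`.

Both cutoff comparisons being strict matters: a ratio of exactly 50, or
a frequency of exactly 80%, does not call. Raising either cutoff can
only shrink the call set (a property the tests assert).

## Curation

* Length filters (`filter_full_length()`, default 750–950 residues
  full-length; `filter_domain_length()`, default 300–400 residues for
  the NB-ARC span) are **inclusive on both ends** — the conventional
  reading of "between X and Y" with no strictness stated — and preserve
  input order.
* `deduplicate()` collapses **exact full-length identity only**, keeping
  the first occurrence. It does not emulate CD-HIT's behaviour at
  `-c 1.00`, where a sequence identical to a proper substring of a
  longer one is also collapsed; exact identity is parameter-free and
  reproducible, at the cost of possibly retaining slightly more
  sequences than a CD-HIT-curated set.
* `extract_clades()` automates what is often done by hand in a tree
  viewer: for each clade it selects the **smallest internal branch**
  that contains all of that clade's reference leaves, none of any other
  clade's, and is well supported. "Well-supported" defaults to support
  ≥ 0.8 — the threshold is deliberately configurable and echoed in the
  provenance output because published analyses rarely quantify it. When
  a tree carries no support values at all the support condition is
  waived (otherwise no clade could ever be extracted); when supports
  are present, a branch lacking one (typically the root) fails it.
  Clades whose references cannot be separated are reported and their
  leaves left unassigned, as are sequences falling outside every
  selected branch. Automated extraction can differ from manual curation
  at poorly supported clade margins; the partition object records the
  failures so such divergences are visible.

## Alignment utilities

`trim_gappy_columns()` removes a column when its gap fraction is
**greater than or equal to** the threshold (default 0.9): a column that
is exactly 90% gaps is removed, matching the documented semantics of
gappy-mode alignment trimmers at the same default.

`map_reference_ranges()` converts ranges given in reference-sequence
residue numbering (1-based, inclusive) into alignment columns by
walking the reference row and skipping its gaps. Mapping is done on the
untrimmed alignment; passing the trimmer's `column_map` re-expresses
the columns in trimmed coordinates, and a reference residue lost to
trimming is an error that reports the original column index — loss must
be detectable, never silent. The eight dimerization stretches of the
helper NLR homodimer (217–220, 238–244, 270–274, 506–513, 528–532,
533–536, 549–554, 559–563 in reference numbering) cover 44 alignment
positions on a gap-free reference, and it is within those 44 columns
that per-clade unique-residue counts are reported
(`count_unique_in_columns()`).

Consensus patterns (`consensus_pattern()`) take the modal residue per
column, breaking exact ties alphabetically (ties are rare and flagged);
the full frequency matrix is returned for logo plotting.

## The synthetic generator

`generate_clade_family()` emulates exactly the statistical structure the
divergence analysis assumes, and nothing more:

* background columns are family-wide invariant (one random residue)
  with probability `background_conservation`, else uniform over the 20
  amino acids — the simplest model exposing both entropy extremes (0
  and 4.32 bits);
* planted sites give the planted clade its diagnostic residue with
  probability `query_fixation` and leak it into the other clades with
  probability `subject_leak`;
* gaps are inserted independently per character after residue
  assignment (this exercises the gap-handling rules without modelling
  indel evolution), and `length_jitter` gaps off sequence ends;
* the companion tree is a star of clades with support 1.0 on each clade
  stem and deliberately low (0.5) support on within-clade branches, so
  that tree-guided extraction at the default 0.8 threshold recovers
  exactly the generating partition — mimicking the common situation of
  well-supported deep clades with poorly resolved shallow structure.

What the generator does **not** emulate: phylogenetically correlated
substitutions, realistic amino-acid exchangeabilities, indel evolution,
or alignment error. Passing the recovery tests therefore shows the
statistic is implemented correctly and behaves as designed under its
own assumptions — not that real clade assignments or real alignments
are error-free.

Default study conditions for recovery experiments are 3 clades × 40
sequences × 300 columns with 5 planted sites per clade and gap rate
0.05. At full fixation and zero leak the caller attains sensitivity 1.0
with zero false calls across 20 seeds. With fixation 0.85 and leak
0.015 the *generating* frequencies pass the rule (ratio 0.85/0.015 ≈
56.7 > 50, callable at 0.85 > 0.8); the *realized* per-site call rate
at 40 sequences per clade is nonetheless well below 1, because binomial
sampling puts the observed query frequency at or below the strict 0.8
cutoff in a sizeable fraction of sites. This is a real property of the
statistic at moderate clade sizes — near-threshold parameters call
unreliably — and the acceptance script reports the realized fraction
rather than hiding it.

`generate_toy_dimer()` places single-atom "residues" on two widely
separated lines and moves each configured chain-B partner to exactly
`cutoff − 0.5` Å from its chain-A residue; every other inter-chain
distance exceeds `cutoff + 2` Å. The construction is verified by brute
force and geometric infeasibility (e.g. one residue asked to contact
two distant partners) is an error.

## Structure interface extraction

* **Contacts** (`find_interface_residues()`): a residue pair is at the
  interface when the *minimum* heavy-atom distance between the two
  residues is ≤ the cutoff (default 6 Å — permissive enough to include
  both short- and long-range interacting residues). Hydrogens are
  discarded on reading; a cryo-EM model at ~4 Å has no reliable
  hydrogen positions. Alternate locations other than blank/'A' are
  dropped and only the first model is read.
* **Stretches** (`derive_stretches()`): each interface residue is
  labeled by the domain(s) of the partner residues it contacts; within
  each (own-domain, partner-domain) class, maximal runs of consecutive
  residue numbers form stretches. Contiguous residues that switch
  partner-domain class split into separate stretches. Families of
  stretches are the unordered domain pairs, numbered by ascending first
  residue; stretches are lettered by ascending start. On an NB-to-LRR
  plus LRR-to-LRR interface this reproduces the conventional 1a–1f /
  2a–2b naming. Domain boundaries are inputs, not constants: published
  schematics rarely pin exact boundary residues.
* **SASA** (`sasa()`): Shrake–Rupley with a deterministic Fibonacci
  spiral lattice (default 960 points per atom) — no random number use,
  so areas are bit-reproducible. Van der Waals radii come from a fixed
  table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, default 1.70 Å) and
  the probe radius defaults to 1.4 Å. At 960 points a lone sphere is
  exact by construction and the two-sphere spherical-cap closed form is
  reproduced within ~0.7%; doubling the lattice moves toy-dimer totals
  by < 0.5%.
* **BSA** (`buried_surface_area()`): per protomer, SASA of the isolated
  chain minus SASA of the same atoms in the complex; the total is the
  sum over protomers, matching the per-protomer-then-total arithmetic
  used in structural reports. Ligands and other heteroatoms are
  excluded by default (`protein_only = TRUE`) since published interface
  areas rarely state their ligand treatment; a flag includes them.

## Pipelines and provenance

`run_divergence_pipeline()` composes the stages in their natural order
(curation → clade assignment → trimming → stretch mapping → entropy →
unique residues) from a flat configuration (an R list or a `key =
value` file), writing TSV reports and a JSON manifest. Outputs carry
the MD5 digest of the configuration that produced them, inputs are
digested into the manifest, and nothing time-dependent is written, so
reruns with identical config and inputs are byte-identical.
`run_interface_pipeline()` does the same for the structural leg;
missing domain boundaries downgrade stretch grouping to a warning while
contacts and BSA are still emitted.

## Numerical choices and degenerate inputs

* Frequencies must sum to 1 within 1e-9; entropy agreement with a
  brute-force oracle is asserted to 1e-12.
* Consensus ties break alphabetically; unique-residue callability uses
  the single majority amino acid (unique above any cutoff > 0.5).
* All-gap columns: undefined entropy (`undefined` class), `NA` ratio,
  `-` consensus.
* An alignment whose every column is gappy enough to be trimmed is an
  error, not an empty result.
* The SASA lattice size trades accuracy for time linearly; 960 points
  keeps the full test suite and the acceptance script within tens of
  seconds on one core while staying inside 1% of the closed forms. The
  recovery experiments use 20 seeds at 3 × 40 × 300; larger replicates
  change none of the reported values at the stated tolerances.

## Known limitations

* Alignment and tree construction are inputs (or delegated to external
  tools); column coordinates are alignment-dependent, so stretch
  mapping can shift at ragged regions under a different aligner. The
  pipeline records input digests but cannot normalize alignments.
* Exact-identity deduplication may retain length-variant near-duplicates
  a CD-HIT-based curation would collapse.
* The unique-residue rule is a threshold classifier, not a statistical
  test: no significance or correction for phylogenetic non-independence
  is attempted, and near-threshold sites call unreliably at moderate
  clade sizes (quantified above).
* SASA is protein-only by default; interface areas computed with
  ligands included will differ where ligands sit near the interface.
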