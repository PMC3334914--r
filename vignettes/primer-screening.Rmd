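---
title: "In-silico design and coverage screening of degenerate metabarcoding primers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico design and coverage screening of degenerate metabarcoding primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Metabarcoding of mixed metazoan samples stands or falls with the primer
pair: a single pair must anneal across phyla whose marker-gene sequences
have diverged for hundreds of millions of years. The mitochondrial
small-subunit (12S) rRNA gene is an attractive marker — faster-evolving
than the nuclear rRNAs, so congeners can be told apart, yet carrying
conserved patches long enough to hold a primer. `primerscope` implements
the in-silico life cycle of such a pair:

1. **Excision** — pull the annotated 12S rRNA feature out of complete
   mitochondrial genome records, in gene orientation, discarding genomes
   whose annotation is absent, ambiguous or implausible.
2. **Design** — scan a multiple alignment of excised genes for conserved
   windows and collapse each into an IUPAC-degenerate consensus primer.
3. **Screening** — locate the best ungapped binding site of each primer in
   every genome of a large collection, count mismatches, and report
   taxonomy-grouped coverage, the positional pattern of mismatches from
   the primer's 3′ end, and predicted amplicon lengths.

The package is deliberately alignment-free at the screening stage: the
mismatch model is positional (no primer–template bulges), which matches
how coverage tables in this literature are computed and keeps the search
exact and fast.

## The matching model

Both primers and targets are strings over the 15-letter IUPAC alphabet.
Write $E(c) \subseteq \{A,C,G,T\}$ for the expansion of code $c$. A primer
position *matches* a target position when $E(p) \cap E(t) \neq \emptyset$.
This intersection semantics has two consequences worth stating:

* a degenerate primer position (say `R`) matches either purine, which is
  exactly what the synthesized oligo mixture does; and
* an `N` in a *target* never counts as a mismatch. Sequencing ambiguity is
  treated neutrally rather than penalised; coverage numbers are therefore
  upper bounds with respect to ambiguous database sequences.

For a primer of length $L$ and a target of length $T$, `best_site()`
evaluates all $T-L+1$ ungapped offsets and returns the one with the fewest
mismatching positions, ties broken to the smallest offset for determinism.
A reverse-orientation primer is reverse-complemented first so the reported
footprint always lies on the target's sense strand, while its mismatch
flags and profiles are still indexed 1..L from the primer's own 3′ end —
the end where a mismatch is most likely to abort extension. The scan is
implemented over 4-bit base masks in C++; the test suite holds it equal to
a brute-force character-set oracle over tens of thousands of random pairs.

Mismatch counts are collapsed into the three-way categorisation customary
for coverage tables — perfect match, one mismatch, two or more — and
grouped by a taxonomic rank read from each record's lineage. Percentages
are printed to two decimals and each row's three counts partition its
group.

Amplicon length is reported as the *insert* — the bases strictly between
the two footprints — following the "product without primers" convention;
`total_length` adds both footprints back.

## Tunable parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `min_len`, `max_len` (validation) | 300, 2500 bp | plausible length range for a mitochondrial SSU rRNA; outside it the annotation is treated as defective |
| `max_ambig_frac` | 0.10 | maximal fraction of non-ACGT bases tolerated in an excised gene |
| `min_length` (regions) | 20 columns | a window must be at least oligo-sized to be a candidate primer site |
| `min_majority_freq` | 0.75 | per-column conservation threshold, computed over unambiguous, ungapped residues |
| `max_gap_fraction` | 0.10 | a primer cannot span an indel-rich column, so gappy columns disqualify |
| `include_freq` | 0.10 | bases at or above this gap-excluded frequency enter the degenerate consensus code |
| `flag_threshold` | 0.35 | positional match fractions below this are flagged as likely amplification risks |
| `band` | 400–600 bp | focal amplicon band for the length summary |

The excision step accepts the annotation dialects commonly used for the
mitochondrial SSU gene (`12S`, `s-rRNA`, `rrnS`, `small subunit ribosomal
RNA`, `12S ribosomal RNA`, `MT-RNR1`), matched case-insensitively against
rRNA features only. Two matching features, or a compound
(`join`/`order`) location, are treated as "ambiguous annotation" and the
record is set aside for manual review rather than silently resolved —
12S is contiguous in mitogenomes, so a compound location is itself
evidence of an annotation problem.

Validation bounds, dialects and all thresholds are explicit arguments:
published screens of this kind state that mis-annotated genomes were
removed but rarely state the rule, so the rule here is configuration with
logged reasons, not a hidden heuristic.

## The synthetic cohort generator

`fixture_spec()` / `generate_dataset()` produce seeded, truth-annotated
datasets so that every stage is testable without downloads. Each record
embeds a gene

```
[left flank][forward site][insert][revcomp(reverse site)][right flank]
```

inside random extragenic background, annotated as an rRNA feature under a
rotating dialect label, on either strand, with a three-level fake lineage
(`Metazoa; <phylum>; <class>`). Primer-site realisations draw each base
from its IUPAC code's expansion; a planted substitution is always drawn
from *outside* the expansion, so the truth mismatch count is exact by
construction (at a fully degenerate `N` position no mismatch is possible
and the planted rate is inert). The generator additionally
rejection-samples flanks and inserts until the planted sites are the
unique best binding sites in the gene, so the truth offsets cannot be tied
by a chance background match.

Defaults emulate the statistical shape of a published metazoan screen:
four phyla of 500 genomes, insert lengths spanning 329–1046 bp with 56/64
of the mass in the 400–600 bp band, a 2% per-position baseline
substitution rate, and one divergent phylum with 70% substitution
hotspots at a handful of 3′-proximal positions — the pattern that makes a
taxon drop into the "two or more mismatches" column of a coverage table.
The companion conservation alignment realises each site column by exact
count allocation (majority base ≈ 78%, every other base of the code ≈
11%) and builds insert columns as shuffled balanced base assignments, so
conserved-region recovery and consensus reconstruction are deterministic
properties, not probabilistic ones. Sites drawn with degeneracy 4 (`N`)
cannot satisfy the majority and inclusion thresholds simultaneously and
are rejected for alignment fixtures; at least 24 rows are required for
the count allocation to clear both thresholds.

What the generator does *not* emulate: phylogenetic correlation between
records, rate heterogeneity along the gene, indels inside primer sites,
and compositional bias. Passing tests therefore demonstrate correctness
of the machinery on data whose truth is known, not that any particular
primer pair will amplify real taxa.

## Numerical and degenerate-input choices

* Column majorities are computed over unambiguous, ungapped residues;
  ties break alphabetically (A < C < G < T) for determinism. A column with
  no unambiguous residue has an undefined majority and can never qualify
  as conserved; inside a consensus region it raises an error.
* Best-site ties break to the smallest offset. Mismatch counting short-
  circuits once the running count exceeds the best so far.
* `degeneracy()` is the product of expansion-set sizes and is returned as
  a double, since 25-mers of `N`s overflow 32-bit integers.
* Coordinates are GenBank-style 1-based inclusive throughout the user
  interface; reverse-complementation happens exactly once, at excision,
  so downstream code only ever sees genes 5′→3′.
* Report writers format percentages to two decimals and fractions to four,
  making repeated runs byte-identical.

## Problem sizes used in the checks

The shipped verification uses 10,000 random primer/target pairs (targets
up to 2 kb) for scanner–oracle equivalence, a 2,000-genome synthetic
cohort (4 phyla × 500) for end-to-end truth recovery, and 100 random
planted-alignment specifications for conservation recovery; the
acceptance script reruns scaled versions of the same computations from a
user-supplied seed. On the synthetic cohort the screen reproduces the
truth table's categories and insert lengths exactly; positional profiles
recover planted rates up to binomial sampling error of the generator
itself.

## Known limitations

* No thermodynamics: annealing temperature, ΔG, GC clamps and 3′-end
  mismatch weighting are out of scope; the mismatch count is unweighted,
  so the categories understate the extra cost of 3′-proximal mismatches —
  which is why the positional profile is reported alongside.
* Ungapped matching only: a target that would bind with a one-base bulge
  is scored as heavily mismatched.
* One best site per primer and target: multi-site templates and
  off-target amplicons are not enumerated.
* Multiple sequence alignment is an external input (any aligner works);
  the package only consumes gapped FASTA.
* Circular genomes whose SSU feature spans the origin are rejected as
  compound locations rather than rotated.
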