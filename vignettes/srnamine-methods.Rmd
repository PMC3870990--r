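---
title: "Methods: small RNA quantification and novel hairpin discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA quantification and novel hairpin discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnamine)
```

srnamine re-implements, as a tested and reusable toolkit, a classic small RNA
sequencing analysis design: quantify mature miRNAs with family-aware
collapsing of ambiguous alignments, call differential expression with a
max-normalized fold-change rule, and mine the reads that match nothing known
for novel miRNA-like hairpins, integrating similarity, structural and
ab-initio evidence into a tiered verdict. This vignette explains the models,
the tunable parameters and the design decisions; the README shows a worked
run.

## Quantification branch

Reads are collapsed to unique (library, sequence) records with copy counts
before any matching; counts are carried, never recomputed. Contaminant
filtering removes reads that occur as substrings of rRNA, tRNA, repeat or
adapter records (exact by default; a substitution budget is available) and
tallies them per class.

Matching against the mature reference is **end-anchored**: a mature sequence
may sit up to `max_shift` (default 2) nt offset from the read terminus, with
any overhang of the mature beyond the read also charged to the shift budget,
and at most `max_mismatch` (default 2) substitutions over the overlap; `N`
counts as a mismatch. The original study mapped color-space reads with
color-space budgets that have no exact base-space equivalent; the 2+2
base-space budget is a conservative, testable translation and both knobs are
configurable.

Multi-hit assignment follows the 5-hit, single-family rule: one hit is
assigned to the mature name; two to five hits are accepted only when all
fall within variations of one miRNA family, and then count to the family key
(reads hitting `hsa-mir-103a-1` and `hsa-mir-103a-2` count as
`hsa-mir-103a`); anything else is discarded as multi-hit. Whether the cap
applies before or after family collapsing is not specified in the original
design; the default caps distinct precursor hits, and `cap_on = "families"`
switches to the post-collapse reading. Family keys default to stripping a
trailing `-<digit>` copy suffix; an explicit family map file overrides.

The per-library ledger (total = contaminant + unmatched + discarded +
assigned copies) is asserted in the tests; no read copy is unaccounted.

## Expression analysis

Profiles are normalized by the **library maximum**: the most abundant
molecule gets 1.0 (or `scale`) and everything else is a relative abundance.
The source description ("normalized using the highest expression value in
the dataset") is ambiguous between a per-library and a global maximum;
per-library is the default because it makes profiles comparable as relative
abundances, and a `global_max` argument provides the other reading. The
published normalized tables are internally inconsistent (the same sample
shows different raw-to-normalized factors), so they are not used as oracles
anywhere.

Differential expression is the pure fold-change rule: a label is called when
both normalized values reach the expression floor and the larger/smaller
ratio is at least `min_fold` (default 2). Zero-vs-nonzero labels are never
fold-tested - they are the province of `unique_expressed()`, which requires
at least `min_unique_count` (default 10) raw copies on the nonzero side. The
floor defaults to the smallest nonzero normalized value observed in either
profile and is applied inclusively (`>=`), so it excludes exactly the zeros;
a literal strict reading would silently drop the smallest observed label
itself. Percentages of shared detected miRNAs are rounded half-up to two
decimals, matching the presentation of the published per-sample tables.

Max-normalization deserves a caveat that the synthetic study makes visible:
the normalizer is itself a measured quantity, so if the most abundant
molecule differs in abundance between libraries, every ratio shifts with it.
Real miRNomes are anchored by a few ubiquitous, highly expressed molecules
(the top ten carry 70-80% of mature-miRNA reads, with miR-21-like molecules
dominating), which stabilizes the maximum; the data generator reproduces
that shape (below).

## Discovery branch

Reads with no contaminant or miRNA match are pooled over libraries, and
those **shorter than 35 nt with at least 10 copies** are selected. The copy
threshold is inclusive by default ("at least ten reads" is used elsewhere in
the source design); `strict_copies` gives the strict "more than 10" reading.

Selected reads are mapped to the genome **exactly**, on both strands (the
original color-space mapper cannot be reproduced in base space; exact
matching keeps the branch deterministic, and a mismatch budget would only
widen clusters). Reads with more than `max_loci` (default 5, by analogy with
the 5-hit rule) placements are dropped and logged. Mapped reads on one
chromosome and strand cluster when separated by at most `max_gap` (default
10) nt - the source is silent on the gap, and 10 nt is small against the
~60 nt scale of a precursor. Each cluster is extended by `flank = 100` nt on
both sides (clamped at chromosome ends), the scale chosen because 98% of
known human precursors are shorter than 135 nt, so a 22 nt read plus
two 100 nt flanks covers virtually any true precursor: a mid-genome 22 nt
read yields a 222 nt putative precursor with the read at offset 100.

A hairpin locus is strand-symmetric to exact mapping (the mature-arm read
also matches the star arm on the reverse strand), so one planted hairpin
surfaces as mirror candidates on the two strands with identical coordinates;
these are collapsed, keeping the plus-strand representative.

**Merging adjacent candidates.** Two candidates on one chromosome and strand
within `max_separation` (default 50) nt are merged when, after folding the
union interval, at least `min_duplex_pairs` (default 5) base pairs connect
one candidate's reads to the other's - the operational reading of "the
original reads covered both sides of the same predicted stem". Base-pair
counting is used instead of helix-arm bookkeeping because it is robust to
bulge-split helices; overlapping read intervals score zero by definition
(they cannot be two arms of a duplex), which keeps same-arm neighbours
separate. Merging runs to a fixpoint and is idempotent.

## Structure module

The built-in folder is a **pair-scored Nussinov dynamic program**, not a
thermodynamic model: scores GC = 3, AU = 2, GU = 1, minimum hairpin loop 3,
and the reported `energy_score` is the negated total - an energy *proxy*,
deliberately never labelled kcal/mol. The optimum is defined
lexicographically (maximize score, then pair count) with a deterministic
tie-break (a base pairs rather than stays unpaired on full ties, and with
its smallest admissible partner), which makes the optimum well-defined and
lets the test suite compare both score and pair count against exhaustive
enumeration of all nested structures for sequences up to 18 nt. Externally
folded structures (Vienna dot-bracket with a trailing free energy) are the
faithful path for real energies and enter through `read_vienna()` and
`parse_dotbracket()`.

Helices are maximal runs of stacked pairs allowing per-arm interior gaps up
to `bulge_tol = 2` nt. Read-vs-stem classification uses the union of helix
*arm intervals* (spanning small bulges), so a read crossing a 1-2 nt bulge
still classifies TOTAL; PARTIAL has no lower bound because the source's
"partially" is not quantified. An independent interval-intersection oracle
checks the classifier on a thousand random structures.

## Evidence integration

**Similarity search** seeds candidate/subject pairs on shared words of
`word_size = 6` (exact, or within one substitution - the standard seeding
sensitivity device), aligns them with local Smith-Waterman (+1/-1, gap -2),
pre-filters by a Karlin-Altschul-style e-value proxy (lambda = ln 3 and
K = 1/3 for this scoring; threshold `max_evalue = 1e-4`) and retains hits
with identity >= 80% and coverage >= 80% **of either side** - so a 22 nt
database subject fully contained in a 222 nt candidate is retained on
subject coverage even though query coverage is ~10%. The proxy is labelled
`evalue_proxy` and is not a BLAST statistic.

**False-positive exclusion** removes candidates overlapping known exons,
candidates matching non-miRNA ncRNA types in the database, and candidates
called tRNAs (externally, or by tRNA-typed annotation overlap), in that
priority order, one primary reason each; hits typed miRNA or
"unclassified RNA" never exclude. Context assignment is strand-aware with
priority exon > intron > intergenic.

**External evidence adapters** read INFERNAL-style tabular output (bit-score
cutoff 25) and a two-column ab-initio score file (cutoff 0.71). Published
candidate tables report ab-initio scores of 0.66-0.70 as predictions despite
the stated 0.71 cutoff; the integrator therefore records sub-threshold
scores and lets the tier rules, not the raw cutoff, weigh them.

**Built-in ab-initio score.** A logistic combination of hairpin features
(global paired fraction, energy proxy per nt, loop length, the read's paired
fraction, longest helix), standing in for an external hairpin classifier.
The weights were calibrated once on the reference synthetic fixture (planted
hairpin precursors as positives, dinucleotide-shuffled precursors plus raw
genome windows as negatives) with ridge-regularized logistic regression, and
are frozen in `abinitio_weights()`; the companion threshold 0.71 mirrors the
external cutoff. On that calibration the classes separate completely
(positives >= 0.77, negatives <= 0.31).

**Verdict tiers** operationalize what the source performed as manual
curation; the mapping is deterministic and monotone in the evidence:

* `excluded` - failed a false-positive rule (dominates everything);
* `strong` - reads cover both arms of one stem (merged or two-arm
  candidate), or a structural family hit covers >= 50% of the read while the
  read lies at least partially in a stem;
* `supported` - at least one positive channel (similarity, family hit,
  ab-initio >= cutoff) with the read in a stem, or two or more channels;
* `weak` - everything else.

**Mature/star proposals** follow the canonical duplex arithmetic: the star
spans the positions paired to the read shifted by the characteristic 2 nt 3'
overhang (star_begin = partner(read_end) + 2, star_end =
partner(read_begin) + 2); a read confined to loops proposes nothing.

## The synthetic study

The raw libraries behind the original analysis were never deposited, so the
package ships a generator whose defaults are the reference study conditions:
a 50 kb genome; 20 known miRNA genes (mature length 19-22 nt, loop 8-15 nt),
a fifth of them planted at two loci sharing one mature sequence to exercise
family collapsing; 5 novel two-arm hairpins (reads simulated from both
arms); 8 contaminant loci cycling rRNA/tRNA/repeat/adapter; 3 unstructured
decoy loci as discovery negatives; two libraries at mean 100 reads per locus
with Poisson sampling; a 4-fold planted change for 30% of known genes; and a
miR-21-like dominant gene at 10x mean expression in both libraries, which
reproduces the top-heavy shape of real miRNomes and anchors
max-normalization. Reads get 0-1 nt end trimming per end (within the
matcher's default terminal-shift budget; up to 2 is supported) and 0.1%
per-base substitution errors. A `fixed_counts` mode replaces Poisson draws
with exact means for exact-count tests, and everything is byte-deterministic
for a fixed seed.

What the generator does **not** emulate: SOLiD color-space error structure,
adapter-ligation chemistry, quality-score realism (qualities are constant
and ignored), isomiR end heterogeneity beyond uniform trimming, expression
overdispersion beyond Poisson, and multi-chromosome genomes. Passing tests
therefore demonstrate algorithmic correctness under clean planted truth, not
performance on real libraries.

## Problem sizes and runtime

The test suite folds 500 random sequences up to 18 nt against exhaustive
enumeration, checks the overlap classifier on 1,000 random structures and
the similarity search against full Smith-Waterman on 200 candidate/subject
pairs, and runs the full pipeline twice on the default fixture to assert
byte-identical reruns; the whole suite completes in about two minutes on one
core, and `scripts/acceptance.R` in about one.

## Known limitations

The folder maximizes pair score, so long random sequences fold into dense
but biologically meaningless structures; discrimination of real hairpins
rests on the read-centric and longest-helix features, not pairedness alone.
Exact-match mapping ignores sequencing errors in the discovery branch (such
reads simply fail selection). The e-value proxy is calibrated only by form,
not against alignment statistics. Verdict tiers are one defensible
operationalization of curation and make no claim to reproduce any particular
manual judgment.
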