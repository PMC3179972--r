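---
title: "orthomerge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthomerge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomerge)
```

This vignette records how the methods in `orthomerge` are defined, which
knobs matter, and where a genuinely open design choice was made — the kind
of detail a maintainer or a careful user needs and a reference page cannot
hold.

## The integration model

The unit of analysis is the ordered gene pair *(a, b)*, *a* in the input
species and *b* in the output species, after all identifiers have been
normalized to integer gene IDs and isoform-level records collapsed.
Integration is a plain set union over the selected source tools, with
provenance: the simple score of a pair is the number of selected tools
predicting it. This deliberately treats tools as exchangeable votes — no
attempt is made to model correlations between tools (two
sequence-clustering tools agreeing is weaker evidence than a tree-based
and a network-based tool agreeing, but modelling that would need a
dependence structure we cannot estimate from the inputs). The weighted
score (below) is the only departure from one-tool-one-vote.

Working at gene level is an assumption, not a convenience: tools that
enumerate isoforms would otherwise inflate both pair counts and apparent
agreement. Collapsing is done before any scoring.

Three decisions here were genuinely open:

* **Ambiguous raw identifiers** (one string resolving to several genes)
  fan out to *all* matching genes, each flagged `ambiguous_source_id`.
  The alternative — dropping them — silently loses genes a disease-focused
  user might care about; the flag keeps the inclusiveness auditable.
* **The "only match" rescue.** The score filters (`s >= 2`, `s >= 3`)
  keep a sub-threshold pair only when it is the query gene's *single*
  candidate. We read "only match" literally; the broader alternative
  (keep the best sub-threshold candidates whenever none pass) is available
  as `rescue = "best_below_threshold"` but is not the default, because it
  re-admits exactly the weak multi-candidate calls the filter exists to
  remove.
* **Best-match ties are all kept.** A gene with two 4-tool candidates has
  no principled winner; both are returned flagged `best_match`, and the
  weighted score is the intended tie-breaker for the user.

Pairs are stored once per ordered species pair; the reverse direction is a
transpose (`transpose_ortho_table()`), not a re-integration, so the two
directions can never disagree. Relationship classes (one-to-one,
one-to-many, many-to-one, many-to-many) are recomputed from partner counts
*within whatever table is being classified* — filtering first and
classifying after gives different (and correct-for-that-view) labels than
classifying the unfiltered table.

## GO semantic similarity and tool weights

Functional coherence is measured on molecular-function annotations only.
Three evidence strata are supported: `MF1` (all codes), `MF2`
(experimental codes EXP, IDA, IPI, IMP, IGI, IEP plus the author/curator
statement codes TAS, NAS, IC) and `MF3` (experimental codes only). The
exact code sets are our reading of "experimental or author/curator
statement"; they are constants in the package, not configuration, because
changing them silently changes every downstream weight. Electronically
inferred annotations (IEA) survive only MF1 — the point of MF2/MF3 is to
avoid scoring a predictor with annotations that were themselves projected
across orthologs.

Information content is corpus-based: `ic(t) = -ln p(t)` with `p(t)` the
fraction of (gene, term) annotations made to `t` or any descendant.
Natural log is used throughout (only ratios of IC matter for Lin, so the
base is cosmetic; it is pinned for reproducibility). Term similarity is
the Lin measure, `2 ic(MICA) / (ic(t1) + ic(t2))`, and gene-pair
similarity the symmetrized best-match average of the term-by-term matrix.
Lin + BMA was chosen over Resnik because it is self-normalizing to [0, 1],
which makes per-tool means comparable across corpora; Resnik is available
behind `method = "resnik"` for users who want raw MICA information.
Edge cases are defined, not left to float arithmetic: identical terms with
positive IC score 1; two terms whose ICs are both zero (the root with
itself) score 0; a gene with no scorable terms makes the pair
*not computable* — excluded from means, never counted as zero, which would
punish tools for annotation sparsity rather than incoherence.

Tool weights are the per-tool mean similarities divided by their median
(midpoint rule for even counts), so the median weight is exactly 1 and
weights are invariant under any positive rescaling of the similarity
scale. A pair's weighted score is the **sum** of its supporting tools'
weights. Sum (rather than mean) was chosen so the weighted score stays on
the same scale as the simple count — equal to it when all weights are 1 —
and preserves the "more tools is more evidence" ordering; a mean would
make a single high-weight tool outrank a five-tool consensus.

## Protein alignment

The aligner is Smith–Waterman with affine gaps (Gotoh's three-state
recursion), BLOSUM62, gap open 10.0 and gap extend 0.5 — the classic
protein defaults of the EMBOSS `water` tool whose display conventions the
match line follows. Numerical conventions, all pinned:

* A gap of length L costs `open + (L − 1) · extend`: the opening charge
  covers the first gap residue. (Aligners differ here; the package's
  tests cross-check scores against `Biostrings::pairwiseAlignment`, whose
  `open + L · extend` convention matches ours at `gapOpening = 9.5`.)
* One optimal alignment is returned. Traceback ties prefer diagonal, then
  gap-in-subject, then gap-in-query; among equal-scoring end cells the
  first in row-major order wins. Co-optimal alignments exist and can
  differ in identity, so determinism here is part of the contract, and
  the test oracle implements the same preference.
* Percent identity and similarity use the **full alignment length**
  including gap columns as denominator (the reporting convention of the
  cited display). All integer percentages are rounded half-up; full
  precision is kept on the result object.
* Residues outside the 20-letter alphabet (X/B/Z/U) are scored through
  the matrix's wildcard row. Selenocysteine (U) is not in BLOSUM62 and is
  scored as X.

Domain identity maps a 1-based inclusive residue interval of one sequence
through the alignment to a column span; gap columns *inside* the span
count in the denominator, and a domain wholly outside the aligned region
yields an `NA` record rather than 0% — "not aligned" and "aligned badly"
are different findings. Multiple isoforms of a gene enter alignment via
the longest (ties broken by smallest accession, purely for determinism).

## Evaluation definitions

Sensitivity is recovered reference pairs over all reference pairs.
Reference matching is unordered — orthology is symmetric, and a predictor
should not fail a benchmark for storing the transposed orientation.
Specificity against the reference queries the predictor with every gene
on either side of the reference set and asks what fraction of the
returned (de-duplicated, unordered) pairs are reference pairs; against a
negative set it is the fraction of lineage-specific genes correctly left
partnerless. Coverage increase is `100 (integrated / tool − 1)` on
distinct-gene counts, half-up to integer percent. Every reported
percentage carries its numerator and denominator so reports can be
audited and re-derived.

## The synthetic world: what it does and does not show

The fixture generator exists so every pipeline stage runs against known
ground truth with no downloads. Defaults (chosen once, as study
conditions):

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 200/species | populates all nine score strata, sub-second tests |
| `n_tools` | 9 | the integrated-tool setting |
| `recall` | 0.4–0.8 spread | the reported per-tool sensitivity band for individual predictors |
| `fp_rate` | 0.05 | small but nonzero, so specificity is informative |
| `frac_one_to_many` / `frac_many_to_one` | 0.20 / 0.08 | input genome less redundant than output (fly → human) |
| `frac_orphan` | 0.15 | lineage-specific genes on both sides, for negative sets |
| `isoform_fraction` | 0.3 | exercises gene-level collapsing on real row mixtures |
| `annotation_density` | 0.8 | some genes unannotated, so not-computable paths run |
| `domain_conservation` / `flank_conservation` | 0.95 / 0.35 | domain identity well above overall identity |

One seed drives named sub-streams (truth, tools, ids, go, seq, disease),
so adding a generator never perturbs the others and a fixed seed is
byte-reproducible.

What the world emulates: tool disagreement as independent Bernoulli
recall, false positives as uniform random pairs, functional coherence as
shared GO branches within true ortholog families, conservation as a
planted domain block inside diverged flanks, and disease-term mapping
with every route represented. What it does **not** emulate: correlated
tool errors (real tools share genome builds and algorithmic families),
realistic GO topology or annotation bias, realistic sequence evolution,
or the long-tailed messiness of real OMIM/GWAS text. Passing tests on
this world therefore demonstrate that the *operations* are correct
(planted rates are recovered exactly, oracles agree, filters are
monotone), not that real-data performance will match any particular
number.

## Disease-term normalization

Term simplification is deterministic: lower-case, strip bracketed
qualifiers, strip punctuation (hyphens kept), collapse whitespace, then
drop trailing comma-separated qualifier phrases (", susceptibility to"
and similar; the list is an argument, with sensible defaults). Routing
precedence is fixed: clinical-synopsis heading map, then MeSH entry
terms on the simplified string, then curated manual overrides, then the
Y01/Y02 keyword rules, then the unmapped report. Precedence order
reflects source reliability — a curated CS-heading match should never be
overridden by a keyword rule. A term may map to several categories
(MeSH is poly-hierarchic) and all are kept, which is why per-category
gene counts do not sum to the total. Anything unmatched lands in the
unmapped report rather than being guessed; unmapped is a reported
outcome everywhere in this package, never an error.

## Problem sizes and budgets in the shipped checks

The test suite runs worlds of 20–100 genes and the acceptance checks use
the 200-gene default world, 200 random short sequence pairs against a
plain-R alignment oracle, and 100 gene pairs against a brute-force BMA
oracle — sizes chosen so the whole suite stays in well under a minute of
compute while still populating every score stratum and mapping route.
The acceptance script's census section feeds the published per-tool and
integrated count tables through the same reporting arithmetic the
package applies to any evaluation, which is a check of the arithmetic,
not a re-derivation of those counts from the nine source datasets.

## Known limitations

* Cross-release reconciliation of the source tools' genome builds is out
  of scope; disagreements caused by build drift look like tool
  disagreement.
* Tool weights assume the GO corpus is informative for the species pair;
  with very sparse MF3 corpora many tools become not-computable and the
  weight vector degenerates toward a single tool.
* The aligner returns one optimal alignment; domain identities on
  co-optimal alignments can differ by a column or two near gap
  boundaries.
* Y01/Y02 keyword lists are seeds, not a classifier: coverage of trait
  and risk-factor phrasing beyond the configured keywords belongs in the
  manual-override table.
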