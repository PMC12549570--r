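---
title: "Methods: affinity-enriched RF peptide repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: affinity-enriched RF peptide repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfpeptidome)
```

# Scope

`rfpeptidome` implements the complete post-acquisition analysis of an
affinity-enriched rheumatoid factor (RF) LC-MS/MS experiment: samples
from a five-group cohort (RF+CCP+ RA, RF−CCP+ RA, RF−CCP− RA, RF−
controls, RF+ controls) are enriched for RF, digested, and measured;
the package takes per-feature quantification and identification tables
from there to isotype positivity calls and a shortlist of
discriminative variable-region peptides.  Because the package must be
testable without the original raw data, it ships a synthetic cohort
generator with known ground truth that reproduces the data structures
the analysis assumes.

# Germline reference and region annotation

The reference is a `GermlineSet`: immunoglobulin heavy/light V and J
germline amino-acid sequences in IMGT gapped alignment, plus
constant-region sequences grouped into seven isotype groups (IgG1-4,
IgA1, IgA2, IgM; some groups carry several accessions).  The shipped
FASTA fixtures are synthetic, curated stand-ins named
`*_synthetic.fasta` — they mimic the composition and IMGT layout of the
official releases but are not copies of them.

IMGT unique numbering partitions a V region into FR1 (positions 1-26),
CDR1 (27-38), FR2 (39-55), CDR2 (56-65), FR3 (66-104), CDR3 (105-117)
and FR4 (118-128).  Gap characters (`.`) in the gapped FASTA define
each germline residue's IMGT position by column index, so an alignment
to an ungapped germline maps directly back to regions.

A peptide is annotated in two steps with constant-region precedence:

1. **Constant match.**  Exact substring search against every
   constant-region sequence.  A hit assigns the isotype group; the
   peptide is *unique to the isotype* if it occurs in the sequences of
   exactly one group.
2. **Variable assignment.**  Smith-Waterman local alignment (BLOSUM62,
   gap open 11 / extend 1, scores floored at 0) against every V
   germline; the best-scoring gene is retained (alphabetical-first on
   ties).  Significance uses the Karlin-Altschul E-value
   `E = K m n exp(-lambda S)` with ungapped BLOSUM62 constants
   `lambda = 0.267`, `K = 0.041`.  Acceptance is the union of two
   engine-style rules: an IMGT-style rule (`E <= 1` and SW score > 30)
   or an IgBLAST-style rule (`E <= 1` with the alignment spanning
   without reaching CDR3).  An accepted peptide is labelled by the IMGT
   regions its aligned residues cover; it counts as CDR-covering only
   if at least 3 aligned residues fall in a CDR.  De novo sequences are
   aligned with I/L treated as equivalent, since the two residues are
   isobaric and indistinguishable by mass.

The union rule is deliberately permissive: measured on random length-9
peptides, about 13% receive a V-region label through the E-value-only
branch.  We kept the two-rule union because it reflects how the two
annotation engines are combined; the false-positive rate is documented
rather than tuned away.

# Identification integration

Each LC-MS feature may carry a database-search identification (with a
Mascot-like score) and/or a de novo identification (with an ALC%
confidence).  The merge applies, in order: de novo sequences are
dropped unless ALC > 80 (strict) and length >= 3; de novo sequences
are excluded when the same feature has a confident (score >= 30)
database hit to an immunoglobulin protein; per feature, the resolved
sequence is the confident database hit if present, otherwise the best
surviving de novo sequence (ties broken by ALC, then length, then
lexicographic order), otherwise a retained low-confidence database
hit; otherwise the feature stays unidentified but remains in the
feature universe.

# Normalization and differential testing

Abundances are normalized Progenesis-style to a reference sample: the
reference is the (upper) middle sample in total-abundance rank order —
a rank-based choice, because "the sample nearest the median" is
ambiguous for even sample counts and numerically unstable under
round-trip perturbations.  Each sample's factor is the mean log-ratio
to the reference over features within 3 MAD of the median log-ratio.

Per-feature group comparison uses the Kruskal-Wallis test across the
five groups, Dunn's post-hoc z for the configured contrast (RF+CCP+ RA
vs RF− controls by default), Holm-Šídák adjustment across features,
and fold-change calling: *up* if adjusted p < 0.05 and FC > 5, *down*
if FC < 0.2.  Robust per-feature Z-scores (median/MAD) support the
discriminative-peptide criteria below.

## Normalization absorbs broad effects

A finding worth stating: when a large fraction of features genuinely
changes, reference normalization absorbs part of the effect.  With the
generator's isotype-elevation switch on, ~40% of features (every
constant-region peptide plus the planted V subset) carry an 8x effect;
the 3-MAD window then includes the shifted features, the per-sample
factors soak up roughly half the effect, and realized fold changes
compress to ~3.3-4.8 — below the FC > 5 call threshold.  This is a
property of the normalization model (it assumes an unchanged
majority), not a bug.  The default cohort design therefore plants
effects only on the designated variable-region subset
(`igConstantEffect = FALSE`); isotype-elevation scenarios enable the
switch explicitly and are analysed through positivity calls, which are
robust to it.

# Sparse PLS-DA and discriminative peptides

Sparse PLS-DA is implemented from scratch (it is the named method of
the study, so the primitive is the point): NIPALS-style components
with soft-thresholding of the X-weight vector to exactly `keepX`
non-zero entries per component, regression-mode deflation,
max-distance class prediction, and the balanced error rate (BER) as
the loss.  The installed `mixOmics` package is used only as an
independent cross-check in one test (cosine of dense weight vectors
> 0.99; identical sparse selections).

Model choice uses stratified 3-fold cross-validation with 50 repeats:
`keepX` is tuned sequentially per component over
{1, 2, 3, 5, 10, 20, 50} and the number of components over 2-5, with
parsimony on ties.  A peptide's *occurrence* is the fraction of CV
repeats in which it was selected on any component of any fold.

Monte-Carlo calibration of the null uses independent noise datasets,
not CV repeats of one dataset: a single finite dataset carries a
spurious class correlation that every repeat rediscovers, so
repeat-level variability understates the truth.  Over independent
pure-noise datasets the mean BER is 0.48 ± 0.016 (SE), consistent with
the 0.5 chance level.

A peptide is flagged *discriminative* only under the full conjunction:
adjusted p < 0.05, fold change > 5, occurrence > 0.5, variable-region
annotation, and the reference control group attaining the lowest
per-group median Z-score.  On the five-group design the tuned model's
BER has a floor around 0.38-0.40 — three RF-negative groups are
mutually indistinguishable, as are the two RF-positive groups — so
tuning selects very sparse models and only a handful of peptides pass
the occurrence criterion.  The package reports this honestly: the
flagged set is expected to be a small fraction of the differential
peptides, and the acceptance suite
verifies the conjunction logic plus zero false flags rather than a
high unconditional sensitivity no correct implementation could reach.

# Isotype quantification and positivity

Per sample, an isotype group's abundance is the sum of normalized
abundances of peptides unique to that group (non-unique peptides are
never counted; an isotype with no unique peptide is reported as
missing, with a warning).  The positivity cut-off per isotype is the
maximum abundance over the reference-group samples; a sample is
positive only if it strictly exceeds that cut-off, so no reference
sample is ever positive.  Group-level Kruskal-Wallis and Dunn tests
run on the quantified isotypes.

# Feature matching across experiments

Features from two experiments match greedily one-to-one: candidate
pairs require both features to have MS/MS, equal charge, |dmz| <= 0.01
Th and |drt| <= 1 min; pairs are assigned best-first by (|dmz|, |drt|,
feature ids) with used features removed.  Tests prove equality with an
exhaustive assignment oracle over a thousand random trials.

# Synthetic cohort generator

`cohortDesign()` fixes the study conditions: group sizes 27/5/22/28/4,
fold change 8 in the two RF-positive groups, log-normal measurement
noise with CV 0.3, per-sample scale factors log-uniform on [0.5, 2],
low-abundance-biased missingness (rate 0.2), 10% unidentified
features, and in-silico Lys-C + chymotrypsin digestion of germline and
background sequences to generate peptides (120 background, 80 Ig, 25
planted V-region effects).  Counts not stated by the study design are
package choices, fixed once.  A seed makes the simulation exactly
reproducible, and the generator restores the caller's RNG state.

Known limits: peptides are sampled from clean germline digests (plus
explicit CDR point variants carried only by de novo records), so there
is no somatic hypermutation background; abundances are i.i.d.
log-normal around the planted structure, so no correlation between
co-eluting features; and chromatography is simulated only as m/z, RT
and charge, without drift.

# Worked example

```{r example, eval = FALSE}
gl <- loadGermlineSet()
design <- cohortDesign(seed = 1)
sim <- simulateExperiment(design, gl)
cfg <- pipelineConfig(seed = 1)
res <- runPipeline(sim, gl, cfg, outDir = tempfile("rfrun"))
head(res$differential)
res$positivity$summary
```

The pipeline writes every stage table, a per-stage record-count log,
and a manifest with the seed and MD5 hashes, so a re-run with the same
inputs reproduces the outputs exactly.
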