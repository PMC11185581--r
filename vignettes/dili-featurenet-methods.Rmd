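---
title: "Methods: stacked proxy-endpoint modelling of drug-induced liver injury"
author: "diliNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked proxy-endpoint modelling of drug-induced liver injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modelling idea

Drug-induced liver injury (DILI) is a leading cause of clinical-trial
failure and post-market withdrawal, and the human outcome is poorly
predicted by any single assay. In vitro endpoints that probe known injury
mechanisms — bile salt export pump (BSEP) inhibition, mitochondrial
depolarization, reactive-metabolite formation — and in vivo endpoints from
animal studies each capture part of the picture, but their mutual
concordance and their concordance with human outcomes are modest.

`diliNet` implements a two-stage ("FeatureNet") scheme. Stage one trains
one tree-ensemble classifier per binary proxy-hepatotoxicity endpoint and
one regressor per pharmacokinetic Cmax endpoint (median plasma
concentration on the negative log-molar, pMolar, scale), using only
chemical structure as input. Stage two predicts those eleven quantities
for every compound in a curated gold-standard DILI list and feeds them —
alongside structural fingerprint bits and physicochemical descriptors —
into a final DILI classifier. The stacked predictions act as a learned,
compressed representation of the biological evidence: each proxy model is
trained on its own (typically larger) corpus, so the final model can draw
on chemistry the gold standard never saw.

Assumptions worth keeping in view: labels are binary per endpoint
(dose and exposure time are not modelled); proxy predictions are functions
of structure, so the stacking can only help insofar as the proxy corpora
cover chemistry or label structure the gold standard lacks; and all models
are trained on the standardized, stereo-free, pH-7-protonated form of each
molecule.

## Compound preparation

Raw SMILES pass a drug-likeness filter applied in a fixed order (the first
failing rule is reported): molecules without carbon, disconnected inputs
with no unique largest organic fragment, metal-only species, and molecules
above 1,500 Da are rejected. The weight cutoff is evaluated on the raw,
pre-fragment-selection molecule, because filtering precedes
standardization in the pipeline.

Standardization applies an ordered transform sequence — alkali metal-bond
disconnection, principal organic fragment selection, canonical
normalization, charge neutralization, isotope removal, stereo removal —
iterated up to five times or until the canonical SMILES reaches a fixed
point. If the trace never stabilizes, the modal SMILES across the
iterations is chosen, with ties broken lexicographically so the outcome is
deterministic. A tautomer-canonicalization hook exists in the declared
step order but is an identity transform: the chemistry toolkit underlying
this package (OpenBabel) ships no tautomer standardizer, and we prefer an
explicit no-op to a partial rule set of our own invention. Consequences
are limited to rare tautomer pairs being kept as distinct records.

Protonation states at hepatic physiological pH 7.0 come from OpenBabel's
substructure-to-pKa transform table; the table identity and backend
version are recorded with every output so runs are reproducible.

Deduplication uses the first 14 characters of the standard InChIKey (the
connectivity "hash layer"), computed on the *pre-protonation* standardized
form — so stereoisomers, isotopologues and protonation microstates of one
skeleton collapse to one record. Conflicting binary labels within one
dataset resolve to the active (toxic) annotation, the usual
evidence-preserving convention in safety data; conflicting continuous
values resolve to their median and are flagged. InChI failures quarantine
the record rather than aborting the run, and every input is conserved:
accepted + rejected + quarantined = inputs.

## Features

The structural block is the standard 2,214-bit layout: a radius-2
circular (Morgan-type/ECFP4) fingerprint folded to 2,048 bits plus the
166 MACCS substructure keys. The MACCS implementation is the
RDKit-derived SMARTS table shipped with OpenBabel; we verified key-by-key
that the fingerprint bit positions coincide with the key identifiers, so
bits can later be traced back to SMARTS patterns for highlighting.

The descriptor block is a 2D graph-topological collection computed from
the molecular graph (constitutional counts, ring statistics, connectivity
and distance indices, kappa shape indices, Moreau–Broto autocorrelations
over atomic mass/electronegativity/covalent radius, bond-polarity
summaries) plus OpenBabel group-contribution properties (logP, TPSA,
molar refractivity, H-bond donor/acceptor counts) and a set of SMARTS
substructure counts. Columns that are undefined anywhere in a corpus
(single-atom molecules leave distance indices undefined) are dropped
corpus-wide and reported; the retained count is therefore a property of
corpus and backend version, not a package constant.

Fifteen physicochemical parameters are computed separately and are never
subject to feature selection: TPSA, H-bond acceptors and donors, fraction
of sp3 carbons, logP, rotatable bonds, rings, assembled rings, aromatic
rings, heteroatoms, stereocenters, positively and negatively charged
atoms, and the NHOH and NO counts. "Assembled rings" is read as the
number of fused ring systems (connected components of the ring-bond
subgraph); the term is non-standard and this interpretation is recorded in
the table provenance. The stereocenter count is a potential-stereocenter
heuristic (saturated carbons with distinct depth-one neighbour
signatures), adequate on stereo-free structures.

Variance-threshold selection is fitted **once** on the leak-free proxy
corpus — thresholds 0.05 for Morgan bits and 0.10 for MACCS keys and
descriptors, comparison strictly greater-than, Bernoulli variance p(1−p)
for binary columns — and the fitted masks are reused unchanged for the
gold standard and for every prediction-time compound. Refitting on the
gold standard would leak test-set information into the feature layout.
Descriptor medians from the fitting corpus are stored so degenerate
values arising in later corpora are imputed consistently.

## Models

All learners are random-forest-mode gradient-boosted tree ensembles
(one boosting round of many parallel bagged trees, learning rate 1,
row subsampling 0.8, per-node feature subsampling). This family was
chosen over classical random-forest implementations because it provides
exact, additive tree-path attributions natively, which stage-two
interpretation relies on; in bagged mode it is the same model family.
One mapping subtlety: the "minimum samples per leaf" hyperparameter is
enforced through a hessian-sum bound, which for logistic loss is about
0.25 per sample at the initial score — the package scales accordingly, so
the declared leaf sizes mean what they say.

Hyperparameters are chosen by successive-halving random search: candidate
configurations are sampled from a declared space (trees 100–1,000, depth
"unbounded"/5–30, minimum samples per split 2–10 and per leaf 1–5,
feature subsampling sqrt/log2/0.3), evaluated under stratified
cross-validation at a small tree budget, and the top third survives to
the next rung with triple the budget. The winner is refit on the full
dataset. Every stage is reproducible from the declared seed.

Decision thresholds maximize Youden's J = sensitivity + specificity − 1
over the midpoints between adjacent distinct predicted probabilities plus
below-minimum and above-maximum sentinels. Ties resolve to the smallest
qualifying threshold (with a 1e−9 tolerance absorbing last-ulp
differences between algebraically equal J values — a real failure mode we
hit in testing); constant probability vectors return 0.5 flagged as
degenerate. Proxy-endpoint thresholds are derived from resubstitution
probabilities of the refit model by default (out-of-fold derivation is
available and recorded); the final DILI threshold always uses inner-fold
out-of-fold estimates on the training data.

The gold standard is split by Butina sphere-exclusion clustering of the
2,048-bit fingerprints at Tanimoto similarity 0.70; clusters are assigned
whole to the training partition (largest first) until it reaches its
target size (80%), and the remainder — by construction the structurally
least similar compounds — forms the held-out test set. Compounds are
sorted by structure key before clustering so the split is platform-stable.

Model selection for the final classifier uses repeated nested
cross-validation: five stratified outer folds, a four-fold inner halving
search per outer fold, thresholds from the inner out-of-fold estimates,
and the whole arrangement repeated with fresh splits (repeat *r* seeds
`seedBase + r`). This produces repeats × folds fold-level reports — the
arithmetic is 5 × 10 = 50 reports under the default specification. The
"best" configuration is defined as the one whose mean outer-validation
AUROC within a repeat is highest across repeats; a fold-level definition
would reward lucky folds.

The 9×9 cross-prediction grid evaluates each endpoint model on every
other endpoint's compounds after removing the model's own training
compounds (the diagonal is resubstitution and flagged as such); whether
to exclude pairwise-overlapping compounds is genuinely open, and
excluding the scorer's training set is the choice that keeps off-diagonal
cells honest without discarding the shared-chemistry signal being
measured.

## Evaluation

All confusion-matrix metrics (sensitivity, specificity, balanced
accuracy, MCC, F1, PPV), the positive likelihood ratio
LR+ = sensitivity/(1 − specificity), average precision, and rank-based
AUROC are computed from first principles and are property-tested against
brute-force recomputation. LR+ is reported as an infinity sentinel with a
flag when specificity is 1. The top-k detection analysis ranks compounds
by descending probability (ties by stable input order) and reports
tp, fp, PPV = tp/k and LR+ = (tp/P)/(fp/N) at that operating point —
the metric of interest when early, low-false-positive detection matters
more than a whole-curve summary. Prediction-vector similarity uses the
positive-match Jaccard coefficient (mutual absences are not matches;
an empty union is 0, flagged). Structural applicability of a test
compound is the mean of its three highest Tanimoto similarities to the
training set. Fold-level metric distributions of two models are compared
with a paired t-test; an identical pairing reports t = 0, p = 1, and a
constant nonzero shift is flagged degenerate rather than tested.

## Interpretation

Per-compound attributions are exact tree-path (SHAP) values from the
ensemble, computed against the training distribution implicit in the
trees; additivity — base value plus contributions equals the model's
log-odds output — is asserted to 1e−6 on every explanation the package
produces. Attributions are reported in log-odds units. For substructure
highlighting, the MACCS key with the largest positive contribution among
the compound's on-bits is mapped back to its SMARTS and matched onto the
molecule to yield atom indices; if no on-key contributes positively the
most protective (negative) key is highlighted with its sign noted. Keys
without a SMARTS definition (isotope and count-only keys) are excluded.
An on-bit whose SMARTS fails to re-match indicates a fingerprint/key-table
mismatch and raises a consistency error rather than a silent empty
highlight. Proxy-endpoint contributions are ranked by absolute value
(ties by registry order) with the top three surfaced, signed.

## The synthetic study corpus

Because the package must be testable end-to-end without any external
download, it ships a generator that emulates the study conditions: nine
binary proxy endpoints of differing sizes (300–1,500 compounds) with
partially overlapping chemistry drawn from a shared pool, two continuous
Cmax endpoints (250 and 180 compounds), and a 600-compound gold standard,
all built from a grammar of 62 drug-like scaffolds and 40 ring-free
decorations validated against the preparation pipeline at generation
time.

Two independent latent causes drive toxicity. A planted toxicophore — an
aromatic/aliphatic nitro substituent, present in 90% of latently toxic
compounds (the remainder are irreducible label error) — gives a local,
fingerprint-visible signal. A lipophilicity latent (computed logP at or
above 2.9, about 35% of the grammar) gives a whole-molecule aggregate
signal that descriptor-based models read directly but local substructure
bits can only approximate, emulating the complementary value of
biological endpoint data over raw structure. The composite DILI latent is
their union (prevalence ≈ 0.6, in the range of the positive fraction of
real curated DILI lists); the gold standard adds 2% label noise, emulating an
adjudicated, curated source, while proxy endpoints carry the heavier
assay-level noise implied by their concordance target. Endpoint families
(human/heterogeneous → composite latent; preclinical/animal →
lipophilicity latent; mechanism assays → toxicophore latent) receive
symmetric label flips calibrated — exactly, via the prevalence-aware
kappa equation solved per family — to a target inter-endpoint Cohen's
kappa of 0.60, the concordance regime reported for real
human-vs-preclinical hepatotoxicity data. Cmax targets are linear in
molecular weight and logP with Gaussian noise (sd 0.3 pMolar).

What the generator does **not** emulate: real pharmacological chemistry
(its grammar is far more regular than a drug corpus), class imbalance
beyond the configured prevalences, dose/exposure effects, and any
mechanism beyond the two planted latents. A green synthetic-recovery
suite therefore demonstrates that the pipeline's machinery — curation,
leak removal, selection, stacking, scaffold-split evaluation,
interpretation — recovers planted signal faithfully; it does not certify
predictive performance on real compounds.

## Numerical and reproducibility choices

* Threshold tie-break tolerance 1e−9; SHAP additivity tolerance 1e−6;
  variance comparison strictly `>`.
* All stochastic steps (config sampling, folds, bagging) derive from
  declared integer seeds; OpenBabel canonicalization, fingerprints and
  the hash layer are deterministic, so fixed seeds reproduce byte-equal
  results.
* Degenerate inputs have defined behaviour rather than errors where the
  pipeline should continue: unparseable SMILES become per-record failure
  rows, InChI failures quarantine, empty Jaccard unions return 0 flagged,
  constant probability vectors return threshold 0.5 flagged.
* Test problem sizes are deliberately compact: the shared unit corpus
  uses three proxy endpoints (150–180 compounds each) and a 120-compound
  gold standard; the synthetic-recovery suite uses the full default
  corpus (600 gold, ~3,000 unique proxy compounds), one fixed generator
  seed, five model seeds, six search candidates and single-repeat nested
  CV. These sizes are the package's choices for a fast, deterministic
  suite; the defaults embedded in the classes (ten repeats, twelve
  candidates) are the ones intended for real analyses.

## Known limitations

* No tautomer canonicalization (identity hook, see above).
* Metal disconnection covers alkali–oxygen ionic bonds written
  covalently; broader organometallic chemistry is filtered out rather
  than standardized.
* The descriptor collection is a compact graph-topological set, not the
  ~1,600-descriptor collections of specialized packages; selection counts
  are corpus- and version-dependent.
* Attributions are associational: a highlighted substructure is evidence
  the model used it, not a causal toxicity mechanism.
* Probability calibration is out of scope; decision thresholds are
  Youden-optimal, not cost-optimal.
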