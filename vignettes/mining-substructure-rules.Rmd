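---
title: "Mining feature-to-substructure rules from MS/MS spectral libraries"
author: "ms2rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining feature-to-substructure rules from MS/MS spectral libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2rules)
```

## The model

Tandem mass spectra of metabolites that share a substructure tend to share
spectral features: characteristic fragment masses and characteristic
neutral losses. `ms2rules` turns a structure-annotated spectral library
into a database of association rules of the form

$$X \Rightarrow Y,$$

where the body $X$ is a set of one to three spectral features — a *Mass*
(neutral exact fragment mass) or an *MDiff* (difference between two
fragment masses), discretized to 4 decimal places — and the head $Y$ is a
single substructure (canonical SMILES). Each rule is a binary classifier
for "this metabolite contains $Y$", and its quality is summarized by a
confusion matrix over the training compounds:

- $\mathrm{Supp}(X) = TP + FP$, spectra containing the feature set $X$;
- $\mathrm{Supp}(Y) = TP + FN$, compounds containing the substructure $Y$;
- $\text{precision} = TP / \mathrm{Supp}(X)$, the probability that the
  metabolite contains $Y$ given that $X$ was observed;
- $\text{recall} = TP / \mathrm{Supp}(Y)$, the probability that $X$ is
  observed given that the metabolite contains $Y$.

Recall is the quantity that separates real from chance associations in
target–decoy comparisons, and it is the score used for FDR control,
ranking and recommendation.

## Workflow

1. **Library ingestion** (`read_mgf()`, `merge_by_structure()`,
   `attach_tree_edges()`): spectra of the same compound (identified by the
   first InChIKey block, falling back to canonical SMILES) are combined
   and duplicate fragments — equal after 4-decimal rounding — removed.
2. **Feature extraction** (`extract_features()`): for *target* training,
   only fragmentation-tree nodes (Mass) and tree edges (MDiff) are used;
   a spectrum with $n$ peaks has $\binom{n}{2}$ pairwise differences, most
   of which carry no structural information, while tree edges are losses
   caused by actual fragmentation reactions. For *decoy* training a
   random 20% subsample of all pairwise differences is drawn. For
   *queries* all pairwise differences plus precursor losses are used, and
   peak masses are neutralized by one proton under the positive-mode
   [M+H]+ assumption.
3. **Substructure generation** (`predefined_substructures()`,
   `cleavage_substructures()`): each training molecule receives the
   predefined patterns it contains plus every fragment obtained by
   disconnecting one or two acyclic single bonds. CHON fragments with
   fewer than five carbon-plus-oxygen atoms are trivial and discarded;
   fragments with other elements (halogens, S, P) are always kept, as are
   only fragments with at least two heavy atoms.
4. **Rule mining** (`mine_rules()`): frequent feature itemsets (support
   $\ge$ `min_supp_x`, default 5) are crossed with every substructure;
   rules with $TP \ge$ `min_tp` (default 5) are kept with exactly counted
   statistics.
5. **FDR control** (`make_decoy_library()`, `run_filter()`): decoy rules
   are mined from a label-preserving randomized library; the *simple FDR*
   at a recall threshold $t$ is
   $\#\{\text{decoy rules} \ge t\} / \#\{\text{target rules} \ge t\}$, and
   the smallest observed target recall achieving the requested level
   (default 1%) becomes the threshold. Target rules strictly above it are
   kept.
6. **Annotation** (`match_rules()`, `aggregate_*()`, `annotate_motif()`):
   a query matches a rule when *every* body feature finds a query feature
   of the same type within the ppm window (20 ppm default). Matched rules
   are ranked by recall and aggregated: *naive* merges identical heads;
   *exhaustive* computes the maximum common substructure (MCS) of every
   "analogous" pair of matched rules (head Tanimoto similarity > 0.5) and
   scores each distinct MCS by the summed recall of its contributing
   rules; *fast* is the exhaustive mode restricted to the 20
   highest-recall matches.

## Design choices

Several points of the procedure are genuinely open; the package settles
them as follows.

**Bond cleavage is restricted to acyclic single bonds.** Cutting a ring
bond leaves the molecule connected and would not produce the expected two
or three fragments per disconnection; multiple bonds are not homolyzed.
Any pair of distinct acyclic (bridge) bonds necessarily yields three
fragments. Synthetically-motivated cut catalogs (BRICS-style bond
environments) select a subset of these same acyclic bonds, so the
all-acyclic enumeration is a superset of such schemes; the
`cleavage_policy` configuration field records the policy in every output.

**Fragment identity is 4-decimal rounding.** Training libraries carry
formula-derived neutral masses, which are identical across spectra to
well below 0.0001 Da; rule bodies print at 4 decimals. Raw, measured
libraries should be pre-clustered; `cluster_feature_values()` provides an
opt-in greedy 20-ppm single-linkage snap.

**The decoy is a peak-pool permutation.** Each decoy record keeps its
structure label and its peak count but receives peaks sampled without
replacement from the pooled peaks of all *other* records. This destroys
any real feature–structure coupling (the null hypothesis of rule mining)
while preserving the global mass distribution and the per-spectrum
feature load. It is a deliberately simple null: it does not preserve
within-spectrum fragmentation topology the way tree-rearrangement decoys
do, so decoy spectra are somewhat "noisier" than rearranged trees would
be. Decoy feature sets contain MDiff features only, drawn as a 20%
subsample; an optional flag to add decoy Mass features exists for
sensitivity analysis but defaults off.

**Threshold semantics are strict.** A rule whose recall equals the chosen
threshold is dropped (`filter_rules()` keeps `recall > t`). The
threshold itself is chosen automatically as the smallest observed target
recall with simple FDR at most `alpha`; visual threshold choice from the
FDR curve remains possible via the exported `fdr_curve()` table.

**Tanimoto similarity uses a hashed linear-path fingerprint** (1024 bits,
paths up to 7 bonds, element- and bond-order-labelled), computed by the
package itself so that the analogous-rule definition is fully
reproducible; the fingerprint name is part of the configuration
fingerprint written into every rule database.

**MCS is the exact connected maximum common induced subgraph** with
element and bond-order matching (aromatic bonds match only aromatic
bonds; charge and stereochemistry are ignored), found by depth-first
extension of partial atom mappings with memoization and a per-pair time
budget (1 s default). On budget exhaustion the pair is skipped with a
warning — for the small fragments that dominate rule heads the search is
exhaustive and deterministic; ties between equally large solutions are
broken by the lexicographically smallest canonical SMILES. When an MCS
contains aromatic bonds outside any ring of the fragment (e.g. a partial
ring walk), those bonds are demoted to single bonds at serialization
time, since aromaticity is undefined for acyclic fragments.

**Scoring counts each rule once.** When several analogous pairs produce
the same MCS, the recall of a rule contributing to several of those pairs
is counted a single time — summing per pair would double-count evidence.

**Recommendation-size filter.** Substructures with fewer than 5 heavy
atoms are suppressed at recommendation time (configurable), not at mining
time: small heads such as a C–Cl stub are statistically sound rules and
stay in the database, but are too generic to report as recommendations.

**Motif annotation.** For externally derived co-occurrence motifs
(lists of fragment/loss features with probabilities), the 50 most
probable features are matched against the database; among rules sharing a
body feature set only the highest-recall rule is kept, recall ties are
resolved by the MCS of the tied heads, and the most frequent resulting
substructure is reported.

## The synthetic-library generator

Real training data with fragmentation trees cannot be shipped, so
`fixture_spec()` / `generate_library()` simulate one. The generator
emulates a curated, formula-annotated, pre-merged library:

- each record is one compound; molecules are drawn with replacement from
  a pool of ~30 small molecules spanning alkanes, phenols, anilines,
  indoles, chlorinated compounds and fused-ring scaffolds;
- each spectrum is a star-shaped fragmentation tree: a pseudo-precursor
  root (drawn from the top quarter of an 80–600 Da window) with one edge
  per fragment, which makes every planted MDiff realizable as a tree
  edge without modeling real fragmentation cascades;
- a planted association emits its feature with probability `emit_prob`
  in spectra of compounds containing its substructure and `leak_prob`
  elsewhere — `emit_prob` *is* the designed recall and `leak_prob`
  controls the designed precision;
- `n_noise_features` uniform-random fragments per spectrum add
  compound-specific noise masses and losses.

What the simulator deliberately does not model: fragment intensities,
correlated fragmentation cascades (non-star trees), measurement error on
masses (features are exactly reproducible after rounding), isotopes, and
negative ion mode. Passing tests on simulated data therefore demonstrate
the correctness of the counting, filtering and aggregation machinery and
the recoverability of designed signal — not robustness to instrument
noise, which a user's real library must bring pre-curated.

Problem sizes used in the shipped test-suite: libraries of 40–200
compounds, parameter-recovery runs with 100 replicates at 200 compounds
per emission probability, and FDR-separation fixtures of 150 compounds
with 20 planted associations. These sizes keep binomial sampling error
(the $3\sqrt{p(1-p)/n}$ band used by the recovery checks) small relative
to the planted effects.

## Numerical and degenerate-input conventions

- All masses round half-even to 4 decimals; feature identity is exact
  string equality of the rounded value plus the feature type.
- `fdr_at_threshold()` returns 0 when neither list has a survivor (0/0)
  and `Inf` when only decoys survive.
- A spectrum with fewer than two peaks has no mass differences; decoy
  subsampling keeps at least one feature.
- Records without a parsable structure are excluded from transactions
  with a warning; unparsable patterns are skipped likewise.
- Rules whose body never occurs in a test library get `NA` precision and
  are flagged not evaluable, as are rules with fewer than 5 test true
  positives.
- Recommendation ties are broken by heavy-atom count (descending), then
  lexicographic SMILES, making all outputs deterministic.

## Known limitations

- Pattern lists are matched as structure fragments (SMILES); general
  SMARTS queries with environment constraints are not supported.
- The MCS time budget makes aggregation of very large heads (20+ heavy
  atoms, e.g. steroid pairs) fall back to pass-through behavior; the
  skipped pairs are reported as warnings.
- The decoy model is a permutation null, not a fragmentation-aware
  rearrangement; decoy rule counts are expected to be conservative
  (fewer, lower-recall decoy rules) on strongly structured libraries.
- Positive ion mode only; the [M+H]+ assumption is a flag, not an adduct
  search.
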