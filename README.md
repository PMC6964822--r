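# ms2rules

Substructure recommendation for tandem mass spectra by association rule
mining.

## The problem

Identifying an unknown metabolite from its MS/MS spectrum usually means
searching a molecular database — which fails for compounds that are not
in any database. A more modest but more robust goal is *substructure*
annotation: spectra of metabolites that share a substructure tend to
share characteristic fragment masses and neutral losses, so those
features can be learned from a structure-annotated spectral library and
used to generate structural hypotheses for any spectrum, including
"unknown unknowns".

`ms2rules` mines a labeled spectral library for association rules

```
X  =>  Y
```

where the body *X* is a set of 1–3 spectral features — a **Mass**
(neutral exact fragment mass) or an **MDiff** (mass difference /
neutral loss), discretized to 4 decimals — and the head *Y* is a single
substructure (canonical SMILES). Each rule is scored by exact counting
over the training compounds:

* `precision = TP / Supp(X)` — probability the metabolite contains *Y*
  given that *X* was observed,
* `recall = TP / Supp(Y)` — probability *X* is observed given that the
  metabolite contains *Y*,

where `Supp(X)` counts spectra containing the feature set, `Supp(Y)`
counts compounds containing the substructure, and `TP` counts both.
Recall separates real from chance associations: rules are
FDR-controlled against a decoy rule set mined from a label-preserving
randomized library (simple FDR = accepted decoys / accepted targets),
and only target rules with recall strictly above the chosen threshold
enter the final database. At query time, all rules whose body features
are found in the spectrum (20 ppm, feature types agreeing) are ranked by
recall and aggregated: rules with similar heads (Tanimoto > 0.5) are
merged into their maximum common substructure (MCS), scored by the sum
of recall of the contributing rules.

For users: metabolomics researchers with a structure-annotated MGF
library (plus fragmentation-tree edge tables) who want a reusable rule
database, and anyone needing ranked substructure hypotheses for query
spectra.

## Worked example

A synthetic library stands in for real training data: 100 simulated
compounds, where every chlorinated compound's spectrum contains the
HCl-loss mass difference (35.9767 Da, the monoisotopic mass of HCl) and
no other spectrum does.

```r
library(ms2rules)
hcl <- round(formula_mass(c(H = 1, Cl = 1)), 4)   # 35.9767 Da

spec <- fixture_spec(
  n_compounds = 100,
  associations = list(
    planted_association("MDiff", hcl, "CCl", emit_prob = 1.0)
  ),
  seed = 1L
)
lib <- generate_library(spec)
#> <ms2_library> 100 target spectra (100 structure-labeled, masses neutral)

tr <- run_train(lib, merge = FALSE)   # simulated libraries are pre-merged
head(as.data.frame(tr$rules), 5)
#>   rule_id          body       head supp_x supp_y tp precision    recall
#> 1       1 MDiff:35.9767        CCl     21     21 21 1.0000000 1.0000000
#> 2       2 MDiff:35.9767 Clc1ccccc1     21     19 19 0.9047619 1.0000000
#> 3       3 MDiff:35.9767   c1ccccc1     21     83 19 0.9047619 0.2289157
#> 4       4 MDiff:35.9767  Cc1ccccc1     21     39  8 0.3809524 0.2051282
#> 5       5 MDiff:35.9767         CC     21     67 10 0.4761905 0.1492537
```

The planted rule (row 1) is perfect by construction: the HCl loss occurs
in all 21 chlorinated compounds (`supp_x = 21`) and only there
(`precision = 1`), and every C–Cl compound shows it (`recall = 1`). Rows
2–5 are the correlated shadows every real library also produces — the
same feature predicting larger or vaguer substructures of the same
molecules, with correspondingly diluted statistics.

Decoy mining and FDR filtering, then annotation of a query spectrum
generated from one of the chlorinated compounds:

```r
dec <- make_decoy_library(lib, seed = 2L)
trd <- run_train(dec, merge = FALSE, seed = 3L)
fl  <- run_filter(tr$rules, trd$rules, alpha = 0.01)
#> threshold: 0.1493 | rules kept: 4 of 5

q   <- generate_query(spec, 1L)
ann <- annotate_spectrum(q, fl$rules, mode = "exhaustive")
head(ann$recommendations, 3)
#>   rank substructure     score n_rules rule_ids
#> 1    1   Clc1ccccc1 1.0000000       1        2
#> 2    2     c1ccccc1 0.2289157       1        3
#> 3    3    Cc1ccccc1 0.2051282       1        4
```

The top recommendation is the chlorobenzene substructure actually
present in the queried compound, scored by the recall of the rules that
suggested it (the 2-atom `CCl` head itself is suppressed by the
5-heavy-atom reporting filter).

## Command line

`scripts/ms2rules.R` wraps the workflow as subcommands
(`simulate`, `train`, `make-decoy`, `filter`, `evaluate`, `annotate`,
`annotate-motif`), reading MGF/TSV and writing TSV with the
configuration fingerprint embedded; see the header of that file for
options.

## Package layout

* `R/` — spectral library IO, molecular-graph chemistry (containment,
  cleavage, Tanimoto, MCS), feature extraction, rule mining, target-decoy
  FDR, annotation, the synthetic-library simulator, and pipeline
  orchestration.
* `vignettes/mining-substructure-rules.Rmd` — the model, its
  assumptions, all tunable parameters, and design decisions.
* `tests/testthat/` — unit, property and end-to-end acceptance tests
  with independent brute-force oracles.
* `inst/extdata/default_patterns.smi` — the default predefined
  substructure pattern list (~60 functional groups and ring systems).
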