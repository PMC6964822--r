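# Synthetic spectral libraries with planted feature-substructure
# associations.
#
# The generator emulates a curated, formula-annotated training library:
# every record is one compound (the library arrives pre-merged), its
# spectrum is a star-shaped fragmentation tree rooted at a pseudo
# precursor, and each planted association emits its feature in the
# spectra of substructure-containing compounds with probability
# `emit_prob` (and in other spectra with `leak_prob`). Emission
# probabilities are therefore the designed recall (and leak controls the
# designed precision) that mining should recover.

#' Define a planted feature-substructure association
#'
#' @param ftype `"Mass"` or `"MDiff"`.
#' @param value Feature value in Da (a neutral fragment mass or a neutral
#'   loss).
#' @param smiles Substructure SMILES whose presence drives emission.
#' @param emit_prob Emission probability in containing compounds (the
#'   designed recall).
#' @param leak_prob Emission probability in non-containing compounds
#'   (controls the designed precision); must not exceed `emit_prob`.
#' @return A `planted_association` object.
#' @export
planted_association <- function(ftype = c("MDiff", "Mass"), value, smiles,
                                emit_prob, leak_prob = 0) {
  ftype <- match.arg(ftype)
  stopifnot(value > 0, emit_prob >= 0, emit_prob <= 1,
            leak_prob >= 0, leak_prob <= emit_prob)
  structure(
    list(ftype = ftype, value = round_mass(value),
         smiles = canonical_smiles(smiles),
         emit_prob = emit_prob, leak_prob = leak_prob),
    class = "planted_association"
  )
}

#' Default molecule pool for simulations
#'
#' About thirty small molecules spanning the chemical families a curated
#' metabolomics library would contain: alkanes and alcohols, phenols,
#' anilines, indoles, chlorinated aromatics and aliphatics, simple acids,
#' and fused-ring (steroid-like) scaffolds.
#'
#' @return Named character vector of SMILES.
#' @export
default_molecule_pool <- function() {
  c(
    octane = "CCCCCCCC",
    decane = "CCCCCCCCCC",
    dodecanol = "CCCCCCCCCCCCO",
    octanoic_acid = "CCCCCCCC(=O)O",
    hexylamine = "CCCCCCN",
    phenol = "Oc1ccccc1",
    p_cresol = "Cc1ccc(O)cc1",
    ethylphenol = "CCc1ccc(O)cc1",
    tyramine = "NCCc1ccc(O)cc1",
    toluene = "Cc1ccccc1",
    ethylbenzene = "CCc1ccccc1",
    styrene = "C=Cc1ccccc1",
    aniline = "Nc1ccccc1",
    n_methylaniline = "CNc1ccccc1",
    benzoic_acid = "OC(=O)c1ccccc1",
    phenylacetate = "O=C(O)Cc1ccccc1",
    cinnamate = "O=C(O)C=Cc1ccccc1",
    indole = "c1ccc2[nH]ccc2c1",
    methylindole = "Cc1c[nH]c2ccccc12",
    tryptamine = "NCCc1c[nH]c2ccccc12",
    indoleacetate = "O=C(O)Cc1c[nH]c2ccccc12",
    chlorobenzene = "Clc1ccccc1",
    dichlorobenzene = "Clc1ccc(Cl)cc1",
    chlorophenol = "Oc1ccc(Cl)cc1",
    chlorotoluene = "Cc1ccc(Cl)cc1",
    chlorohexane = "CCCCCCCl",
    chloroaniline = "Nc1ccc(Cl)cc1",
    naphthalene = "c1ccc2ccccc2c1",
    methylnaphthalene = "Cc1cccc2ccccc12",
    decalin = "C1CCC2CCCCC2C1",
    hydrindanone = "O=C1CCC2CCCCC12"
  )
}

#' Specify a synthetic spectral library
#'
#' Validates that every planted substructure is contained in at least one
#' pool molecule and that planted feature values fit below the simulated
#' precursor masses.
#'
#' @param n_compounds Number of compounds (records) to simulate; molecules
#'   are drawn from the pool with replacement, each draw treated as a
#'   distinct compound.
#' @param molecule_pool Character vector of SMILES
#'   ([default_molecule_pool()] by default).
#' @param associations List of [planted_association()] objects.
#' @param n_noise_features Number of random noise fragments per spectrum.
#' @param mass_range Simulated mass window in Da (precursors are drawn
#'   from the top quarter of the window).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `fixture_spec` object. The containment matrix of pool
#'   molecules versus planted substructures is precomputed in attribute
#'   `"containment"`.
#' @export
fixture_spec <- function(n_compounds, molecule_pool = default_molecule_pool(),
                         associations = list(), n_noise_features = 3L,
                         mass_range = c(80, 600), seed = 1L) {
  stopifnot(n_compounds >= 1L, length(molecule_pool) >= 1L,
            mass_range[1L] > 0, mass_range[2L] > mass_range[1L])
  root_floor <- mass_range[2L] - 0.25 * (mass_range[2L] - mass_range[1L])
  contain <- matrix(FALSE, length(molecule_pool), length(associations))
  for (ai in seq_along(associations)) {
    a <- associations[[ai]]
    stopifnot(inherits(a, "planted_association"))
    if (a$value >= root_floor) {
      stop("association value ", a$value, " does not fit below the ",
           "simulated precursor masses (>= ", round(root_floor, 1), " Da)")
    }
    contain[, ai] <- vapply(molecule_pool, contains_substructure,
                            logical(1L), sub = a$smiles)
    if (!any(contain[, ai])) {
      stop("planted substructure ", a$smiles,
           " is contained in no pool molecule")
    }
  }
  structure(
    list(n_compounds = as.integer(n_compounds),
         molecule_pool = molecule_pool,
         associations = associations,
         n_noise_features = as.integer(n_noise_features),
         mass_range = as.numeric(mass_range),
         seed = as.integer(seed)),
    class = "fixture_spec",
    containment = contain
  )
}

# One simulated compound record. Star tree: the precursor root is the
# parent of every fragment, so each planted MDiff d is realized by a child
# at root - d and each planted Mass m by a child node at m.
.simulate_record <- function(spec, idx, mol_i, contain_row) {
  rng <- spec$mass_range
  root <- round_mass(stats::runif(1L, rng[2L] - 0.25 * (rng[2L] - rng[1L]), rng[2L]))
  children <- numeric(0L)
  emitted <- logical(length(spec$associations))
  for (ai in seq_along(spec$associations)) {
    a <- spec$associations[[ai]]
    p <- if (contain_row[ai]) a$emit_prob else a$leak_prob
    if (stats::runif(1L) < p) {
      emitted[ai] <- TRUE
      children <- c(children, if (a$ftype == "MDiff") root - a$value else a$value)
    }
  }
  if (spec$n_noise_features > 0L) {
    children <- c(children,
                  stats::runif(spec$n_noise_features, rng[1L], root - 1))
  }
  children <- unique(round_mass(children))
  children <- children[children > 0 & children < root]
  peaks <- data.frame(
    mass = c(root, children),
    intensity = round(stats::runif(1L + length(children), 10, 1000))
  )
  edges <- if (length(children) > 0L) {
    data.frame(parent_mass = root, child_mass = children)
  } else {
    NULL
  }
  rec <- spectrum_record(
    spectrum_id = sprintf("cpd_%04d", idx),
    peaks = peaks,
    precursor_mz = NA_real_,
    structure = spec$molecule_pool[[mol_i]],
    tree_edges = edges
  )
  list(record = rec, emitted = emitted, root = root)
}

#' Generate a synthetic spectral library
#'
#' Draws molecules from the pool with replacement and simulates one
#' spectrum per compound (see [fixture_spec()]). The result carries a
#' `"ground_truth"` attribute: per record, the drawn molecule, the root
#' mass, which associations its molecule contains and which features were
#' actually emitted.
#'
#' @param spec A [fixture_spec()].
#' @return A target [spectral_library()] with tree edges.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  contain <- attr(spec, "containment")
  sim <- with_seed(spec$seed, {
    mol_idx <- sample.int(length(spec$molecule_pool), spec$n_compounds,
                          replace = TRUE)
    lapply(seq_len(spec$n_compounds), function(i) {
      c(.simulate_record(spec, i, mol_idx[i], contain[mol_idx[i], ]),
        list(mol = mol_idx[i]))
    })
  })
  lib <- spectral_library(lapply(sim, `[[`, "record"), label = "target")
  mol_idx <- vapply(sim, `[[`, integer(1L), "mol")
  mol_names <- if (is.null(names(spec$molecule_pool))) {
    as.character(mol_idx)
  } else {
    names(spec$molecule_pool)[mol_idx]
  }
  attr(lib, "ground_truth") <- data.frame(
    spectrum_id = vapply(sim, function(s) s$record$spectrum_id, character(1L)),
    molecule = mol_names,
    root = vapply(sim, `[[`, numeric(1L), "root"),
    contains = I(lapply(sim, function(s) contain[s$mol, ])),
    emitted = I(lapply(sim, `[[`, "emitted")),
    stringsAsFactors = FALSE
  )
  lib
}

#' Generate a query spectrum from a simulated compound
#'
#' Re-simulates the library deterministically and converts the chosen
#' record to query form: peak masses and the precursor are protonated
#' (+1.00728 Da) and the fragmentation tree is dropped, as for a raw
#' instrument spectrum.
#'
#' @param spec A [fixture_spec()].
#' @param compound_index Record index in `1:n_compounds`.
#' @return An [spectrum_record()] with protonated masses.
#' @export
generate_query <- function(spec, compound_index) {
  stopifnot(compound_index >= 1L, compound_index <= spec$n_compounds)
  lib <- generate_library(spec)
  rec <- lib$records[[compound_index]]
  root <- attr(lib, "ground_truth")$root[compound_index]
  spectrum_record(
    spectrum_id = paste0(rec$spectrum_id, "_query"),
    peaks = data.frame(mass = rec$peaks$mass + .PROTON_MASS,
                       intensity = rec$peaks$intensity),
    precursor_mz = root + .PROTON_MASS,
    structure = rec$structure
  )
}
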