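# Internal helpers shared across modules.

# Monoisotopic masses of the elements handled by the simulator and the
# triviality filter. Values in Da.
.ELEMENT_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473
)

# Mass of a proton, used to neutralize [M+H]+ query peaks.
.PROTON_MASS <- 1.00728

#' Monoisotopic mass of a molecular formula
#'
#' Computes the neutral monoisotopic mass from explicit element counts.
#' Used by the simulator to plant chemically meaningful neutral-loss
#' features (for example the HCl loss at 35.9767 Da).
#'
#' @param counts Named integer vector of element counts, e.g.
#'   `c(H = 1, Cl = 1)`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(H = 1, Cl = 1))  # HCl, 35.9767 after 4-decimal rounding
#' @export
formula_mass <- function(counts) {
  el <- names(counts)
  bad <- setdiff(el, names(.ELEMENT_MASS))
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  sum(.ELEMENT_MASS[el] * as.numeric(counts))
}

# Canonical mass discretization: all feature values and peak identities are
# compared after rounding to 4 decimal places.
round_mass <- function(x) round(x, 4L)

fmt_mass <- function(x) sprintf("%.4f", x)

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG stream afterwards. Keeps all simulator/decoy draws
# reproducible without clobbering the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
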