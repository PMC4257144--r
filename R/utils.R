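# Shared constants, conditions and small helpers.

# 20 standard amino acids, three-letter -> one-letter.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_123 <- setNames(names(AA_321), unname(AA_321))
STANDARD_AA <- sort(unname(AA_321))

# Boltzmann constant [J/K], elementary charge [C], vacuum permittivity [C^2/(J m)].
.KB <- 1.380649e-23
.EC <- 1.602176634e-19
.EPS0 <- 8.8541878128e-12

#' Coulomb constant in kT/e units
#'
#' Returns `e^2 / (4 pi eps0 kB T)` expressed in Angstrom, i.e. the constant
#' `C` such that a unit point charge in a homogeneous medium of relative
#' dielectric `eps` produces a potential `C / (eps * r)` kT/e at distance
#' `r` Angstrom. At 298 K this is about 560.7 A (Bjerrum length in water
#' ~7.2 A).
#'
#' @param temperature temperature in Kelvin.
#' @return scalar, Angstrom.
#' @export
coulomb_constant <- function(temperature = 298) {
  .EC^2 / (4 * pi * .EPS0 * .KB * temperature) * 1e10
}

#' Convert potentials between kT/e and millivolt
#'
#' `1 kT/e` equals `kB T / e` volts (about 25.7 mV at 298 K).
#'
#' @param x numeric potentials.
#' @param temperature temperature in Kelvin.
#' @return numeric of the same length.
#' @export
kte_to_mv <- function(x, temperature = 298) x * (.KB * temperature / .EC) * 1e3

#' @rdname kte_to_mv
#' @export
mv_to_kte <- function(x, temperature = 298) x / ((.KB * temperature / .EC) * 1e3)

# Classed error helper: all package errors inherit "escapist_error".
abort <- function(message, class, data = list()) {
  stop(structure(
    class = c(class, "escapist_error", "error", "condition"),
    c(list(message = message, call = NULL), data)
  ))
}

# Log to stderr; level gating is handled by option escapist.verbose.
log_msg <- function(...) {
  if (isTRUE(getOption("escapist.verbose", TRUE))) {
    message(...)
  }
  invisible(NULL)
}

check_aa1 <- function(code, what = "residue code") {
  bad <- !(code %in% STANDARD_AA)
  if (any(bad)) {
    abort(
      sprintf(
        "invalid %s: %s (must be one of the 20 standard one-letter codes)",
        what, paste(unique(code[bad]), collapse = ", ")
      ),
      "escapist_invalid_residue"
    )
  }
  invisible(code)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
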