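# Partial charges and radii for the 20 standard residues.
#
# The bundled table is a heavy-atom charge set in the spirit of PARSE:
# hydrogen charges are collapsed onto their bonded heavy atom, so backbone
# N/CA carry 0 and the C=O dipole keeps +0.55/-0.55. Sidechains are neutral
# except for the formal charges of Asp/Glu (-1, on the carboxylate) and
# Lys/Arg (+1, on NZ / the guanidinium CZ); His is neutral at pH 7. If the
# atoms that carry a residue's formal charge are absent (e.g. structures
# truncated at Cbeta), the missing charge is restored onto CB so that every
# residue sums to its integer formal charge.

BACKBONE_CHARGES <- c(N = 0, CA = 0, C = 0.55, O = -0.55, OXT = -0.55)

SIDECHAIN_ATOMS <- list(
  A = "CB",
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  N = c("CB", "CG", "OD1", "ND2"),
  D = c("CB", "CG", "OD1", "OD2"),
  C = c("CB", "SG"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  G = character(),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  M = c("CB", "CG", "SD", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG", "CD"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  V = c("CB", "CG1", "CG2")
)

# Non-zero sidechain partial charges (all others in SIDECHAIN_ATOMS are 0).
SIDECHAIN_CHARGES <- list(
  D = c(CG = 0.10, OD1 = -0.55, OD2 = -0.55),
  E = c(CD = 0.10, OE1 = -0.55, OE2 = -0.55),
  N = c(CG = 0.55, OD1 = -0.55),
  Q = c(CD = 0.55, OE1 = -0.55),
  K = c(NZ = 1.0),
  R = c(CZ = 1.0)
)

# Integer formal charge per residue at neutral-pH defaults.
FORMAL_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

# van der Waals radii by element, Angstrom.
ELEMENT_RADII <- c(C = 1.70, N = 1.50, O = 1.40, S = 1.85, H = 1.00)

atom_element <- function(atom) {
  el <- substr(gsub("^[0-9]+", "", atom), 1L, 1L)
  el[grepl("^[0-9]*H", atom)] <- "H"
  el
}

internal_charge_radius <- function(aa, atom) {
  el <- atom_element(atom)
  radius <- unname(ELEMENT_RADII[el])
  charge <- numeric(length(atom))
  known <- logical(length(atom))
  for (i in seq_along(atom)) {
    a <- atom[i]
    if (el[i] == "H") {                       # implicit-hydrogen model
      charge[i] <- 0; radius[i] <- ELEMENT_RADII[["H"]]; known[i] <- TRUE
    } else if (a %in% names(BACKBONE_CHARGES)) {
      charge[i] <- BACKBONE_CHARGES[[a]]; known[i] <- TRUE
    } else if (a %in% SIDECHAIN_ATOMS[[aa[i]]]) {
      sc <- SIDECHAIN_CHARGES[[aa[i]]]
      charge[i] <- if (!is.null(sc) && a %in% names(sc)) sc[[a]] else 0
      known[i] <- TRUE
    }
  }
  list(charge = charge, radius = radius, known = known)
}

#' Assign partial charges and radii to a structure
#'
#' With `forcefield = "internal"` (default) charges and radii come from the
#' bundled heavy-atom table described above; per-residue charges always sum
#' to the residue's integer formal charge at neutral pH (missing charged
#' sidechain atoms have their charge restored onto CB). With
#' `forcefield = "pdb2pqr"` the external PDB2PQR program is run with the
#' PARSE force field and the resulting PQR is read back; this requires the
#' `pdb2pqr` executable on the PATH (or `options(escapist.pdb2pqr = ...)`).
#'
#' @param structure a `protein_structure`.
#' @param forcefield `"internal"` or `"pdb2pqr"`.
#' @return a `charged_structure`: the input with per-atom `charge`
#'   (elementary charges) and `radius` (Angstrom) columns and a
#'   `forcefield` element.
#' @export
assign_charges_radii <- function(structure,
                                 forcefield = c("internal", "pdb2pqr")) {
  forcefield <- match.arg(forcefield)
  if (forcefield == "pdb2pqr") {
    return(run_pdb2pqr(structure))
  }
  at <- structure$atoms
  cr <- internal_charge_radius(at$aa, at$atom)
  if (any(!cr$known)) {
    bad <- unique(paste0(at$aa[!cr$known], ":", at$atom[!cr$known]))
    abort(sprintf("atoms not covered by the internal charge table: %s",
                  paste(bad, collapse = ", ")),
          "escapist_unmapped_atom")
  }
  at$charge <- cr$charge
  at$radius <- cr$radius
  # Restore each residue's integer formal charge if charge-carrying atoms
  # are missing; deficits go onto CB, else CA.
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  for (k in unique(rkey)) {
    rows <- which(rkey == k)
    aa <- at$aa[rows[1]]
    deficit <- FORMAL_CHARGE[[aa]] - sum(at$charge[rows])
    if (abs(deficit) > 1e-9) {
      carrier <- rows[match(c("CB", "CA"), at$atom[rows])]
      carrier <- carrier[!is.na(carrier)][1]
      if (!is.na(carrier)) {
        at$charge[carrier] <- at$charge[carrier] + deficit
      }
    }
  }
  out <- structure
  out$atoms <- at
  out$forcefield <- "internal"
  class(out) <- unique(c("charged_structure", class(structure)))
  out
}

# External PDB2PQR adapter (PARSE force field); requires the binary.
run_pdb2pqr <- function(structure) {
  exe <- getOption("escapist.pdb2pqr", Sys.which("pdb2pqr"))
  if (!nzchar(exe) || !file.exists(exe)) {
    abort(paste0("pdb2pqr executable not found; install it or set ",
                 "options(escapist.pdb2pqr = '/path/to/pdb2pqr')"),
          "escapist_missing_executable",
          data = list(binary = "pdb2pqr", config_key = "escapist.pdb2pqr"))
  }
  tmp_pdb <- tempfile(fileext = ".pdb")
  tmp_pqr <- tempfile(fileext = ".pqr")
  on.exit(unlink(c(tmp_pdb, tmp_pqr)))
  write_structure(structure, tmp_pdb)
  status <- system2(exe, c("--ff=PARSE", shQuote(tmp_pdb), shQuote(tmp_pqr)),
                    stdout = FALSE, stderr = TRUE)
  if (!file.exists(tmp_pqr)) {
    abort(sprintf("pdb2pqr failed: %s", paste(status, collapse = "\n")),
          "escapist_backend_error")
  }
  out <- parse_structure(tmp_pqr, id = structure$id)
  out$forcefield <- "PARSE (pdb2pqr)"
  out
}

#' Net charge of a charged structure, by residue
#'
#' @param charged a `charged_structure`.
#' @return data frame with `chain`, `resno`, `aa`, `charge`.
#' @export
residue_charges <- function(charged) {
  stopifnot(inherits(charged, "charged_structure"))
  at <- charged$atoms
  agg <- stats::aggregate(
    at$charge,
    by = list(chain = at$chain, resno = at$resno, insert = at$insert),
    FUN = sum
  )
  names(agg)[4] <- "charge"
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  map <- setNames(at$aa[first], key[first])
  agg$aa <- unname(map[paste(agg$chain, agg$resno, agg$insert, sep = "|")])
  agg[order(agg$chain, agg$resno), c("chain", "resno", "aa", "charge")]
}
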