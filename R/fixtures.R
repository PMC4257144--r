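# Synthetic fixtures: idealized peptides, noise decoys, analytic charge
# systems. Everything here is a pure function of its arguments and seed, so
# the whole pipeline is testable without downloading any structure.

# Ideal peptide internal geometry (Engh/Huber-style averages), Angstrom and
# degrees. Frozen so fixtures are stable across versions.
PEPTIDE_GEOMETRY <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_ca_cb = 110.1,
  t_n_c_ca_cb = 122.6,   # improper fixing the L configuration
  omega = 180
)

deg <- function(x) x * pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

# Natural-extension-reference-frame placement: returns d with |c-d| = bond,
# angle(b, c, d) = angle and torsion(a, b, c, d) = torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg(angle); tor <- deg(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

#' Build an idealized peptide structure
#'
#' Constructs backbone N, CA, C, O and sidechain CB coordinates from ideal
#' bond lengths and angles at the requested backbone dihedrals, with trans
#' peptide bonds and tetrahedral CB placement; glycine residues get no CB.
#' Optional isotropic Gaussian coordinate jitter emulates experimental /
#' model noise and is fully determined by `seed`.
#'
#' @param sequence one-letter amino-acid string over the 20 standard codes.
#' @param phi,psi backbone dihedrals in degrees, recycled along the chain
#'   (defaults are an extended conformation).
#' @param jitter coordinate noise standard deviation, Angstrom.
#' @param seed integer seed for the jitter; `NULL` uses the current RNG.
#' @param id structure identifier.
#' @param chain chain identifier.
#' @return a `protein_structure`.
#' @export
generate_peptide <- function(sequence, phi = -120, psi = 130, jitter = 0,
                             seed = NULL, id = "peptide", chain = "A") {
  aa <- strsplit(sequence, "")[[1]]
  if (!length(aa)) abort("empty sequence", "escapist_invalid_residue")
  check_aa1(aa)
  stopifnot(jitter >= 0)
  n <- length(aa)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  g <- PEPTIDE_GEOMETRY

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- pi - deg(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] - 180)
    if (aa[i] != "G") {
      CB[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ],
                            g$b_ca_cb, g$a_c_ca_cb, g$t_n_c_ca_cb)
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    names_i <- c("N", "CA", "C", "O", if (aa[i] != "G") "CB")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ],
                 if (aa[i] != "G") CB[i, ])
    rows[[i]] <- data.frame(
      chain = chain, resno = i, insert = "", aa = aa[i], atom = names_i,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, rows)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(seed, {
      atoms[, c("x", "y", "z")] +
        matrix(rnorm(3L * nrow(atoms), sd = jitter), ncol = 3)
    })
  }
  rownames(atoms) <- NULL
  new_protein_structure(id, atoms)
}

#' Perturb a structure with isotropic coordinate noise
#'
#' @param structure a `protein_structure`.
#' @param noise per-coordinate Gaussian standard deviation, Angstrom.
#' @param seed integer seed; `NULL` uses the current RNG.
#' @param id identifier of the perturbed copy.
#' @return a `protein_structure`.
#' @export
perturb_structure <- function(structure, noise, seed = NULL,
                              id = paste0(structure$id, "_perturbed")) {
  stopifnot(noise >= 0)
  at <- structure$atoms
  if (noise > 0) {
    at[, c("x", "y", "z")] <- with_seed(seed, {
      at[, c("x", "y", "z")] + matrix(rnorm(3L * nrow(at), sd = noise),
                                      ncol = 3)
    })
  }
  out <- structure
  out$atoms <- at
  out$id <- id
  out
}

#' All-atom RMSD between two conformations of the same structure
#'
#' Plain coordinate RMSD without superposition (the decoy generator applies
#' noise in the native frame).
#'
#' @param a,b `protein_structure`s with identical atom ordering.
#' @return scalar RMSD, Angstrom.
#' @export
structure_rmsd <- function(a, b) {
  stopifnot(nrow(a$atoms) == nrow(b$atoms))
  d <- as.matrix(a$atoms[, c("x", "y", "z")]) -
    as.matrix(b$atoms[, c("x", "y", "z")])
  sqrt(mean(rowSums(d^2)))
}

#' Generate a decoy family on disk
#'
#' Writes one target directory in the layout consumed by
#' [evaluate_decoy_set()]: `native.pdb` plus `count_per_level` noisy copies
#' per noise level (`decoy_s<level>_<i>.pdb`), and a `manifest.json`
#' recording the generating parameters and seed.
#'
#' @param native a `protein_structure`.
#' @param noise_levels per-coordinate noise SDs, Angstrom.
#' @param count_per_level decoys per level.
#' @param dir parent directory (created if needed).
#' @param seed integer seed; the family is a pure function of
#'   (native, levels, counts, seed).
#' @param target_id directory name; defaults to the native's id.
#' @return invisibly, a list with `dir`, `native`, `decoys` (paths) and
#'   `manifest`.
#' @export
generate_decoy_family <- function(native, noise_levels = c(1, 2),
                                  count_per_level = 5L, dir = tempfile(),
                                  seed = 1L, target_id = native$id) {
  stopifnot(all(noise_levels >= 0), count_per_level >= 1L)
  tdir <- file.path(dir, target_id)
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  native_path <- file.path(tdir, "native.pdb")
  write_structure(native, native_path)
  decoys <- character()
  with_seed(seed, {
    for (lv in noise_levels) {
      for (i in seq_len(count_per_level)) {
        nm <- sprintf("decoy_s%g_%02d", lv, i)
        dst <- perturb_structure(native, lv, seed = NULL, id = nm)
        p <- file.path(tdir, paste0(nm, ".pdb"))
        write_structure(dst, p)
        decoys <- c(decoys, p)
      }
    }
  })
  manifest <- list(
    target = target_id, seed = seed, noise_levels = noise_levels,
    count_per_level = count_per_level,
    n_residues = nrow(native$residues),
    generator = "escapist::generate_decoy_family"
  )
  jsonlite::write_json(manifest, file.path(tdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = tdir, native = native_path, decoys = decoys,
                 manifest = manifest))
}

#' Analytic charge systems for solver validation
#'
#' Builds the named closed-form test system as a `charged_structure`:
#' a single point charge (`"point"`), a Born ion of given radius
#' (`"born"`), or two opposite charges at a given separation (`"dipole"`).
#'
#' @param kind `"point"`, `"born"` or `"dipole"`.
#' @param q charge magnitude, elementary charges.
#' @param radius atom radius, Angstrom (the Born radius for `"born"`).
#' @param separation dipole charge separation, Angstrom.
#' @param center system center, Angstrom.
#' @return a `charged_structure`.
#' @export
synthetic_charge_system <- function(kind = c("point", "born", "dipole"),
                                    q = 1, radius = 2, separation = 4,
                                    center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  mk <- function(x, y, z, charge, rad) {
    data.frame(chain = "A", resno = seq_along(x), insert = "", aa = "A",
               atom = "CB", x = x + center[1], y = y + center[2],
               z = z + center[3], occ = 1, charge = charge, radius = rad,
               stringsAsFactors = FALSE)
  }
  atoms <- switch(kind,
    point = mk(0, 0, 0, q, radius),
    born = mk(0, 0, 0, q, radius),
    dipole = mk(c(-separation / 2, separation / 2), c(0, 0), c(0, 0),
                c(q, -q), radius)
  )
  st <- new_protein_structure(paste0("synthetic_", kind), atoms)
  st$forcefield <- sprintf("synthetic(%s)", kind)
  st
}
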