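# Structure model and PDB/PQR input/output.
#
# A protein_structure holds an atom table (one row per kept atom) and a
# residue table ordered as in the file; residue indices (`idx`) are 1-based
# positions within each chain, matching the summation bounds of the learning
# and scoring phases. Author numbering (`resno`, `insert`) is kept alongside
# for chain-break detection.

new_protein_structure <- function(id, atoms) {
  required <- c("chain", "resno", "insert", "aa", "atom", "x", "y", "z", "occ")
  stopifnot(all(required %in% names(atoms)))
  if (nrow(atoms) == 0L) {
    abort(sprintf("structure '%s' contains no standard residues", id),
          "escapist_empty_structure")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates", "escapist_parse_error")
  }
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    insert = atoms$insert[first],
    aa = atoms$aa[first],
    stringsAsFactors = FALSE
  )
  residues$idx <- stats::ave(seq_len(nrow(residues)), residues$chain,
                             FUN = seq_along)
  structure(
    list(id = id, atoms = atoms, residues = residues),
    class = c(if (!is.null(atoms$charge)) "charged_structure",
              "protein_structure")
  )
}

#' Read a protein structure from a PDB or PQR file
#'
#' Keeps standard amino-acid `ATOM` records only (HETATM, waters and
#' nonstandard residues such as MSE are dropped). For alternate locations the
#' highest-occupancy conformer is kept; ties go to altloc "A", then
#' lexicographic order. Files ending in `.pqr` are read as PQR, with per-atom
#' charge and radius taken from the occupancy and B-factor columns.
#'
#' @param path path to a PDB or PQR file.
#' @param model_index 1-based model to read from multi-model files.
#' @param id structure identifier; defaults to the file name without extension.
#' @return a `protein_structure` (a `charged_structure` for PQR input) with
#'   elements `id`, `atoms` (data frame: chain, resno, insert, aa, atom,
#'   x, y, z, occ, and for PQR charge, radius) and `residues` (chain, resno,
#'   insert, aa, idx), residues ordered as in the file, `idx` 1-based per
#'   chain.
#' @export
parse_structure <- function(path, model_index = 1L,
                            id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "escapist_io_error")
  }
  is_pqr <- grepl("\\.pqr$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_pqr) bio3d::read.pqr(path, rm.alt = FALSE) else
      bio3d::read.pdb(path, multi = model_index > 1L, rm.alt = FALSE,
                      verbose = FALSE),
    error = function(e) {
      abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
            "escapist_parse_error")
    }
  )
  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model_index) {
      abort(sprintf("model %d not present in '%s'", model_index, path),
            "escapist_parse_error")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  keep <- at$type == "ATOM" & at$resid %in% names(AA_321)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    abort(sprintf("no standard amino-acid residues in '%s'", path),
          "escapist_empty_structure")
  }
  insert <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- at$o
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = insert,
    aa = unname(AA_321[at$resid]),
    atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    occ = occ,
    alt = alt,
    stringsAsFactors = FALSE
  )
  if (is_pqr) {
    atoms$charge <- at$o     # PQR: occupancy column holds the partial charge
    atoms$radius <- at$b     # and the B-factor column the radius
    atoms$occ <- 1
  }
  atoms <- resolve_altlocs(atoms)
  atoms$alt <- NULL
  if (!is_pqr && any(atoms$occ < 0 | atoms$occ > 1)) {
    abort(sprintf("occupancy outside [0, 1] in '%s'", path),
          "escapist_parse_error")
  }
  st <- new_protein_structure(id, atoms)
  if (is_pqr) st$forcefield <- "pqr-file"
  st
}

# One atom per (residue, atom name): highest occupancy wins; ties prefer
# altloc "A", then the lexicographically smallest tag.
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  pref <- ifelse(atoms$alt == "A", 0L, 1L)
  ord <- order(key, -atoms$occ, pref, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  # restore file order
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Write a structure as a PDB file
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno,
    resid = unname(AA_123[at$aa]),
    chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    elety = at$atom,
    o = at$occ,
    b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Write a charged structure as a PQR file
#'
#' Charges go to the occupancy column and radii to the B-factor column.
#'
#' @param charged a `charged_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(charged, path) {
  stopifnot(inherits(charged, "charged_structure"))
  at <- charged$atoms
  bio3d::write.pqr(
    file = path,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno,
    resid = unname(AA_123[at$aa]),
    chain = at$chain,
    elety = at$atom,
    o = at$charge,
    b = at$radius
  )
  invisible(path)
}

#' @export
print.protein_structure <- function(x, ...) {
  nchain <- length(unique(x$residues$chain))
  cat(sprintf(
    "<%s> '%s': %d residue(s) in %d chain(s), %d atoms%s\n",
    class(x)[1], x$id, nrow(x$residues), nchain, nrow(x$atoms),
    if (!is.null(x$atoms$charge))
      sprintf(", net charge %+.3f", sum(x$atoms$charge)) else ""
  ))
  invisible(x)
}

#' Enumerate scorable consecutive residue pairs
#'
#' Per chain, yields the pairs (n, n+1) for positions n from
#' `1 + ignore_nterm` through `N - ignore_cterm - 1` (1-based, inclusive),
#' skipping the stated number of residues at each terminus. Pairs spanning a
#' chain break (author-numbering gap greater than 1) are omitted, and pairs
#' are never formed across chains. A chain too short to contribute yields no
#' pairs (this is not an error).
#'
#' @param structure a `protein_structure`.
#' @param ignore_nterm,ignore_cterm number of residues to skip at the N and C
#'   terminus of every chain (default 3 each; terminal charges perturb the
#'   electrostatic potential).
#' @return data frame with one row per pair: `chain`, `n` (position of the
#'   first residue), `resno_first`, `resno_second`, `aa_first`, `aa_second`.
#' @export
consecutive_pairs <- function(structure, ignore_nterm = 3L, ignore_cterm = 3L) {
  stopifnot(ignore_nterm >= 0L, ignore_cterm >= 0L)
  res <- structure$residues
  out <- lapply(split(res, res$chain), function(rc) {
    rc <- rc[order(rc$idx), , drop = FALSE]
    N <- nrow(rc)
    lo <- 1L + as.integer(ignore_nterm)
    hi <- N - as.integer(ignore_cterm) - 1L
    if (hi < lo) return(NULL)
    n <- lo:hi
    gap <- rc$resno[n + 1L] - rc$resno[n]
    ok <- gap == 1L | (gap == 0L & rc$insert[n + 1L] != rc$insert[n])
    n <- n[ok]
    if (!length(n)) return(NULL)
    data.frame(
      chain = rc$chain[n], n = n,
      resno_first = rc$resno[n], resno_second = rc$resno[n + 1L],
      insert_first = rc$insert[n], insert_second = rc$insert[n + 1L],
      aa_first = rc$aa[n], aa_second = rc$aa[n + 1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(
      chain = character(), n = integer(),
      resno_first = integer(), resno_second = integer(),
      insert_first = character(), insert_second = character(),
      aa_first = character(), aa_second = character(),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
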