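# Shared fixtures: all built in code, nothing downloaded.

# Residue alphabet with well-separated sidechain charge patterns; used for
# synthetic learning sets so every pair type collects enough samples.
FIXTURE_ALPHABET <- c("A", "D", "F", "K", "S", "T")

random_sequences <- function(n, len, alphabet = FIXTURE_ALPHABET) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Standard synthetic learning set: idealized peptides with small coordinate
# jitter, deterministic in `seed`.
make_learning_set <- function(n = 50, len = 30, jitter = 0.05, seed = 7,
                              alphabet = FIXTURE_ALPHABET) {
  with_seed <- get("with_seed", asNamespace("escapist"))
  with_seed(seed, {
    seqs <- random_sequences(n, len, alphabet)
    lapply(seq_along(seqs), function(i) {
      generate_peptide(seqs[i], jitter = jitter, seed = NULL,
                       id = sprintf("learn%03d", i))
    })
  })
}

# Potentials provider with per-residue-type base potentials plus i.i.d.
# Gaussian per-atom noise: the generative model with known pair EPD means
# base[a] - base[b]. Draws from the current RNG stream.
type_potentials_fun <- function(base, noise_sd = 0) {
  force(base); force(noise_sd)
  function(st) {
    at <- st$atoms[st$atoms$atom %in% c("N", "CA", "C", "CB"), ]
    phi <- unname(base[at$aa])
    phi[is.na(phi)] <- 0
    if (noise_sd > 0) phi <- phi + rnorm(length(phi), sd = noise_sd)
    data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
               atom = at$atom, phi = phi, stringsAsFactors = FALSE)
  }
}

# Minimal template around given pair means (sd 10, n 100).
manual_template <- function(means, mode = c("CB", "CB")) {
  entries <- data.frame(pair = names(means), mean = unname(means),
                        sd = 10, n = 100L, stringsAsFactors = FALSE)
  get("new_epd_template", asNamespace("escapist"))(
    mode = mode, entries = entries[order(entries$pair), ],
    sd_thresh = 50, min_samples = 1L,
    provenance = list(backend = "manual")
  )
}

# Hand-written fixed-width ATOM records for parser edge cases that the
# package writer does not emit (altlocs, insertion codes).
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resid, chain, resno, icode, x, y, z, occ, 0)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
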