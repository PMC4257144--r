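# Learning phase: signed electrostatic potential differences (EPD) between
# named atoms of consecutive residues, pooled per canonical amino-acid pair.
#
# Pair keys are order-independent: the two one-letter codes are sorted
# alphabetically, and when the observed order had to be swapped the EPD sign
# is flipped (multfactor -1), so "AC" statistics include both A->C and C->A
# observations. The difference is always taken N-terminal minus C-terminal
# before canonicalization.

#' Feature-extraction configuration
#'
#' @param atom_p,atom_q atom names in the first and second residue of each
#'   pair. The usual modes are CB/CB (sidechain proxy, the discriminating
#'   feature), CA/CA and C/N (backbone controls).
#' @param mode shorthand overriding `atom_p`/`atom_q`: `"cb"`, `"ca"` or
#'   `"cn"`.
#' @param ignore_nterm,ignore_cterm residues skipped at the chain termini.
#' @param sd_thresh standard-deviation cutoff in kT/e: pair types whose EPD
#'   spread exceeds this are excluded from the template (default 50).
#' @param min_samples minimum observation count for a pair type (or a
#'   sequence-distance bin) to be retained (default 30).
#' @param exclude_cysteine drop every pair containing cysteine, whose EPDs
#'   are broad and uninformative apart from the CC pair.
#' @return a `feature_config` list.
#' @export
feature_config <- function(atom_p = "CB", atom_q = "CB", mode = NULL,
                           ignore_nterm = 3L, ignore_cterm = 3L,
                           sd_thresh = 50, min_samples = 30L,
                           exclude_cysteine = FALSE) {
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("cb", "ca", "cn"))
    ap <- switch(mode, cb = c("CB", "CB"), ca = c("CA", "CA"),
                 cn = c("C", "N"))
    atom_p <- ap[1]; atom_q <- ap[2]
  }
  stopifnot(sd_thresh > 0, min_samples >= 1,
            ignore_nterm >= 0, ignore_cterm >= 0)
  structure(
    list(atom_p = atom_p, atom_q = atom_q,
         ignore_nterm = as.integer(ignore_nterm),
         ignore_cterm = as.integer(ignore_cterm),
         sd_thresh = sd_thresh, min_samples = as.integer(min_samples),
         exclude_cysteine = isTRUE(exclude_cysteine)),
    class = "feature_config"
  )
}

#' Canonical amino-acid pair key
#'
#' Sorts the two one-letter codes alphabetically; `multfactor` is +1 when
#' the observed order was already sorted and -1 when it was swapped (the EPD
#' sign is reversed accordingly, making pair statistics order-independent).
#' Vectorized over both arguments.
#'
#' @param type_a,type_b one-letter codes of the first and second residue.
#' @return data frame with `key` (sorted two-letter string) and `multfactor`
#'   (+1 or -1).
#' @export
canonical_pair <- function(type_a, type_b) {
  check_aa1(c(type_a, type_b))
  swapped <- type_a > type_b
  data.frame(
    key = ifelse(swapped, paste0(type_b, type_a), paste0(type_a, type_b)),
    multfactor = ifelse(swapped, -1, 1)
  )
}

# Sign convention: for symmetric atom modes (CB-CB, CA-CA) swapping the
# residue order negates the difference exactly, so the canonical sign flip
# makes statistics order-independent. For asymmetric modes (the C-N peptide
# bond) the feature belongs to the bond itself and is already
# order-independent; flipping would split each pair type into an artificial
# +/- mixture, so the raw sign is kept.
pair_multfactor <- function(cp, config) {
  if (identical(config$atom_p, config$atom_q)) cp$multfactor else 1
}

lookup_phi <- function(potentials, chain, resno, insert, atom) {
  key <- paste(potentials$chain, potentials$resno, potentials$insert,
               potentials$atom, sep = "|")
  potentials$phi[match(paste(chain, resno, insert, atom, sep = "|"), key)]
}

# Vectorized EPD extraction over a pair table; pairs whose atoms carry no
# potential (e.g. glycine in CB mode) are dropped.
epd_observations <- function(potentials, pairs, config, structure_id = NA) {
  if (nrow(pairs) == 0L) {
    return(data.frame(key = character(), value = numeric(),
                      chain = character(), n = integer(),
                      structure_id = character()))
  }
  phi_p <- lookup_phi(potentials, pairs$chain, pairs$resno_first,
                      pairs$insert_first, config$atom_p)
  phi_q <- lookup_phi(potentials, pairs$chain, pairs$resno_second,
                      pairs$insert_second, config$atom_q)
  cp <- canonical_pair(pairs$aa_first, pairs$aa_second)
  value <- (phi_p - phi_q) * pair_multfactor(cp, config)
  keep <- !is.na(value)
  data.frame(
    key = cp$key[keep], value = value[keep],
    chain = pairs$chain[keep], n = pairs$n[keep],
    structure_id = rep(structure_id, sum(keep)),
    stringsAsFactors = FALSE
  )
}

#' EPD of one consecutive residue pair
#'
#' Raw difference `phi(atom_p of residue n) - phi(atom_q of residue n+1)`,
#' multiplied by the canonical-pair sign factor. Returns `NULL` when either
#' residue lacks the required atom (glycine has no CB; the skip is logged).
#'
#' @param potentials per-atom potentials from [atom_potentials()].
#' @param pair one row of [consecutive_pairs()].
#' @param config a [feature_config()].
#' @return list with `key`, `value` (kT/e), `multfactor`, or `NULL` if the
#'   pair cannot be evaluated.
#' @export
compute_epd <- function(potentials, pair, config = feature_config()) {
  obs <- epd_observations(potentials, pair, config)
  if (nrow(obs) == 0L) {
    log_msg(sprintf("skipping pair %s%s at %s:%d (missing %s/%s potential)",
                    pair$aa_first[1], pair$aa_second[1], pair$chain[1],
                    pair$n[1], config$atom_p, config$atom_q))
    return(NULL)
  }
  cp <- canonical_pair(pair$aa_first[1], pair$aa_second[1])
  list(key = obs$key[1], value = obs$value[1], multfactor = cp$multfactor[1])
}

default_potentials_fun <- function(backend, params) {
  force(backend); force(params)
  function(st) {
    atom_potentials(assign_charges_radii(st), params, backend = backend)
  }
}

#' Learn per-pair EPD means from a set of structures
#'
#' The learning phase: extracts the signed canonical EPD of every scorable
#' consecutive residue pair in every structure, pools the observations per
#' canonical pair key, and keeps the pairs whose standard deviation is at
#' most `config$sd_thresh` and whose sample count is at least
#' `config$min_samples`. The retained means are the template against which
#' candidate models are scored.
#'
#' Pooling is over observations by default (every pair occurrence weighs
#' equally); `pooling = "per_protein"` first averages within each structure
#' and then across structures, which differs when structures contribute
#' unequal counts. The retention filter always uses the pooled-observation
#' standard deviation.
#'
#' @param structures list of `protein_structure` objects.
#' @param config a [feature_config()].
#' @param backend `"builtin"` or `"external"` (ignored when
#'   `potentials_fun` is given).
#' @param params a [solver_params()].
#' @param pooling `"observations"` (default) or `"per_protein"`.
#' @param potentials_fun optional function `structure -> potentials` data
#'   frame, replacing the electrostatics backend (used for synthetic
#'   generative models in tests).
#' @return an `epd_template`: list with `mode` (atom pair), `entries` (data
#'   frame `pair`, `mean`, `sd`, `n`), `dropped` (same columns, filtered
#'   out), `sd_thresh`, `min_samples`, `provenance`.
#' @export
learn_features <- function(structures, config = feature_config(),
                           backend = c("builtin", "external"),
                           params = solver_params(),
                           pooling = c("observations", "per_protein"),
                           potentials_fun = NULL) {
  backend <- match.arg(backend)
  pooling <- match.arg(pooling)
  stopifnot(length(structures) >= 1L)
  pf <- potentials_fun %||% default_potentials_fun(backend, params)
  obs <- do.call(rbind, lapply(structures, function(st) {
    pots <- pf(st)
    pairs <- consecutive_pairs(st, config$ignore_nterm, config$ignore_cterm)
    epd_observations(pots, pairs, config, structure_id = st$id)
  }))
  if (is.null(obs) || nrow(obs) == 0L) {
    abort("no EPD observations could be extracted from the learning set",
          "escapist_empty_template")
  }
  grp <- split(obs$value, obs$key)
  n <- vapply(grp, length, integer(1))
  sds <- vapply(grp, function(v) if (length(v) > 1L) sd(v) else 0, numeric(1))
  means <- if (pooling == "observations") {
    vapply(grp, mean, numeric(1))
  } else {
    per <- split(obs, obs$key)
    vapply(per, function(d) {
      mean(vapply(split(d$value, d$structure_id), mean, numeric(1)))
    }, numeric(1))
  }
  entries <- data.frame(pair = names(grp), mean = unname(means),
                        sd = unname(sds), n = unname(n),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$pair), , drop = FALSE]
  keep <- entries$sd <= config$sd_thresh & entries$n >= config$min_samples
  if (config$exclude_cysteine) {
    keep <- keep & !grepl("C", entries$pair, fixed = TRUE)
  }
  dropped <- entries[!keep, , drop = FALSE]
  entries <- entries[keep, , drop = FALSE]
  rownames(entries) <- rownames(dropped) <- NULL
  backend_name <- if (is.null(potentials_fun)) backend else "custom"
  new_epd_template(
    mode = c(config$atom_p, config$atom_q),
    entries = entries, dropped = dropped,
    sd_thresh = config$sd_thresh, min_samples = config$min_samples,
    provenance = list(
      backend = backend_name, pooling = pooling,
      n_structures = length(structures),
      n_observations = nrow(obs),
      created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
    )
  )
}

new_epd_template <- function(mode, entries, dropped = NULL, sd_thresh = 50,
                             min_samples = 1L, provenance = list()) {
  stopifnot(all(c("pair", "mean", "sd", "n") %in% names(entries)))
  structure(
    list(mode = mode, entries = entries,
         dropped = dropped %||% entries[0, ],
         sd_thresh = sd_thresh, min_samples = min_samples,
         provenance = provenance),
    class = "epd_template"
  )
}

#' @export
print.epd_template <- function(x, ...) {
  cat(sprintf(
    "<epd_template> %s-%s EPD means: %d pair type(s) retained, %d dropped (sd > %g or n < %d)\n",
    x$mode[1], x$mode[2], nrow(x$entries), nrow(x$dropped),
    x$sd_thresh, x$min_samples
  ))
  if (nrow(x$entries)) {
    print(head(x$entries, 10), row.names = FALSE)
    if (nrow(x$entries) > 10) cat(sprintf("  ... %d more\n",
                                          nrow(x$entries) - 10))
  }
  invisible(x)
}

#' @export
summary.epd_template <- function(object, ...) {
  e <- object$entries
  cat(sprintf("EPD template, atoms %s-%s, backend %s\n",
              object$mode[1], object$mode[2],
              object$provenance$backend %||% "unknown"))
  cat(sprintf("  %d retained pair types (of %d observed)\n", nrow(e),
              nrow(e) + nrow(object$dropped)))
  if (nrow(e)) {
    cat(sprintf("  mean EPD range [%.1f, %.1f] kT/e; SD range [%.1f, %.1f]\n",
                min(e$mean), max(e$mean), min(e$sd), max(e$sd)))
    cat(sprintf("  samples per pair: median %d, total %d\n",
                as.integer(stats::median(e$n)), sum(e$n)))
  }
  invisible(object)
}

#' EPD spread as a function of sequence separation
#'
#' Generalizes the consecutive-pair feature to residue pairs (n, n + d) and
#' reports, for one canonical pair type, the standard deviation and sample
#' count at each separation d. Bins with fewer than `config$min_samples`
#' observations are omitted. In native structures the spread grows with d:
#' consecutive residues constrain each other's electrostatic environment
#' more than distant ones.
#'
#' @param structures list of `protein_structure` objects.
#' @param pair_key canonical two-letter pair key, e.g. `"DF"`.
#' @param max_distance largest sequence separation to report.
#' @param config a [feature_config()].
#' @inheritParams learn_features
#' @return data frame `distance`, `sd`, `n`.
#' @export
epd_vs_distance <- function(structures, pair_key, max_distance = 10L,
                            config = feature_config(),
                            backend = c("builtin", "external"),
                            params = solver_params(),
                            potentials_fun = NULL) {
  backend <- match.arg(backend)
  stopifnot(max_distance >= 1L, nchar(pair_key) == 2L)
  pf <- potentials_fun %||% default_potentials_fun(backend, params)
  vals <- vector("list", max_distance)
  for (st in structures) {
    pots <- pf(st)
    res <- st$residues
    for (ch in unique(res$chain)) {
      rc <- res[res$chain == ch, , drop = FALSE]
      rc <- rc[order(rc$idx), , drop = FALSE]
      N <- nrow(rc)
      for (d in seq_len(max_distance)) {
        lo <- 1L + config$ignore_nterm
        hi <- N - config$ignore_cterm - d
        if (hi < lo) next
        n <- lo:hi
        ok <- (rc$resno[n + d] - rc$resno[n]) == d
        n <- n[ok]
        if (!length(n)) next
        cp <- canonical_pair(rc$aa[n], rc$aa[n + d])
        sel <- cp$key == pair_key
        if (!any(sel)) next
        n <- n[sel]
        phi_p <- lookup_phi(pots, rc$chain[n], rc$resno[n], rc$insert[n],
                            config$atom_p)
        phi_q <- lookup_phi(pots, rc$chain[n + d], rc$resno[n + d],
                            rc$insert[n + d], config$atom_q)
        v <- (phi_p - phi_q) * pair_multfactor(cp[sel, , drop = FALSE],
                                               config)
        vals[[d]] <- c(vals[[d]], v[!is.na(v)])
      }
    }
  }
  out <- data.frame(
    distance = seq_len(max_distance),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else NA_real_,
                numeric(1)),
    n = vapply(vals, length, integer(1))
  )
  out[out$n >= config$min_samples & !is.na(out$sd), , drop = FALSE]
}

# ---- template file format --------------------------------------------------

#' Write / read an EPD template file
#'
#' Tab-separated with a header line `PAIR MEAN SD N` and `#`-prefixed
#' provenance comments (atom mode, backend, filter settings). Reading back a
#' written template reproduces its entries exactly. Rows with an unsorted
#' pair key are normalized on read (key sorted, mean sign flipped) with a
#' warning; malformed numeric fields are an error naming the line.
#'
#' @param template an `epd_template`.
#' @param path file path.
#' @return `write_template` returns `path` invisibly; `read_template`
#'   returns an `epd_template`.
#' @export
write_template <- function(template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mode: %s %s", template$mode[1], template$mode[2]),
    sprintf("# sd_thresh: %g", template$sd_thresh),
    sprintf("# min_samples: %d", template$min_samples),
    sprintf("# backend: %s", template$provenance$backend %||% "unknown"),
    sprintf("# source: %s",
            template$provenance$source %||%
              sprintf("%s structures, %s observations",
                      template$provenance$n_structures %||% "?",
                      template$provenance$n_observations %||% "?")),
    "PAIR\tMEAN\tSD\tN"
  ), con)
  e <- template$entries
  writeLines(sprintf("%s\t%g\t%g\t%d", e$pair, e$mean, e$sd, e$n), con)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("template file not found: %s", path), "escapist_io_error")
  }
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (cm in comments) {
    m <- regmatches(cm, regexec("^#\\s*([a-z_]+):\\s*(.*)$", cm))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) {
    abort(sprintf("template '%s' has no data rows", path),
          "escapist_parse_error")
  }
  header <- strsplit(trimws(lines[body_idx[1]]), "\t|\\s+")[[1]]
  if (!identical(toupper(header[1:4]), c("PAIR", "MEAN", "SD", "N"))) {
    abort(sprintf("template '%s': expected header PAIR MEAN SD N on line %d",
                  path, body_idx[1]), "escapist_parse_error")
  }
  rows <- body_idx[-1]
  entries <- data.frame(pair = character(), mean = numeric(),
                        sd = numeric(), n = integer(),
                        stringsAsFactors = FALSE)
  for (ln in rows) {
    f <- strsplit(trimws(lines[ln]), "\t|\\s+")[[1]]
    if (length(f) < 4) {
      abort(sprintf("template '%s' line %d: expected 4 fields, got %d",
                    path, ln, length(f)), "escapist_parse_error")
    }
    nums <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(nums))) {
      abort(sprintf("template '%s' line %d: non-numeric field in '%s'",
                    path, ln, lines[ln]), "escapist_parse_error")
    }
    pair <- f[1]
    if (nchar(pair) != 2L) {
      abort(sprintf("template '%s' line %d: bad pair key '%s'",
                    path, ln, pair), "escapist_parse_error")
    }
    a <- substr(pair, 1, 1); b <- substr(pair, 2, 2)
    if (a > b) {
      warning(sprintf("template line %d: unsorted pair key '%s' normalized",
                      ln, pair))
      pair <- paste0(b, a)
      nums[1] <- -nums[1]
    }
    entries <- rbind(entries, data.frame(
      pair = pair, mean = nums[1], sd = nums[2], n = as.integer(nums[3]),
      stringsAsFactors = FALSE
    ))
  }
  entries <- entries[order(entries$pair), , drop = FALSE]
  rownames(entries) <- NULL
  mode <- strsplit(meta$mode %||% "CB CB", "\\s+")[[1]]
  new_epd_template(
    mode = mode, entries = entries,
    sd_thresh = as.numeric(meta$sd_thresh %||% 50),
    min_samples = as.integer(meta$min_samples %||% 1),
    provenance = list(backend = meta$backend %||% "unknown",
                      source = meta$source %||% path)
  )
}

#' The packaged Cbeta reference template
#'
#' Sixteen high-confidence consecutive-residue Cbeta EPD pair means (kT/e)
#' learned from a nonredundant set of high-resolution crystal structures
#' with the reference APBS electrostatics, shipped with the package as
#' `extdata/table3_cbeta.tsv`.
#'
#' @return an `epd_template`.
#' @export
reference_template <- function() {
  read_template(system.file("extdata", "table3_cbeta.tsv",
                            package = "escapist", mustWork = TRUE))
}
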