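# Quality-assessment phase: PDscore and decoy-set evaluation.
#
# The PDscore of a structure is the mean absolute deviation of its observed
# canonical pair EPDs from the learned template means, taken over the pairs
# whose type is present in the template ("NumberCompared"). Pairs filtered
# out of the template (high spread, too few samples, glycine in CB mode) do
# not enter the denominator. By the Boltzmann/thermodynamic argument the
# native structure is expected to minimize the PDscore among candidates.

#' PDscore of a structure against a learned template
#'
#' @param structure a `protein_structure`.
#' @param template an `epd_template` (its atom mode must match `config`).
#' @param config a [feature_config()].
#' @param backend,params,potentials_fun as in [learn_features()].
#' @param first_chain_only score only the first chain.
#' @return a `pd_score`: list with `pdscore` (kT/e), `number_compared`,
#'   `contributions` (per-pair data frame: chain, n, pair, observed,
#'   template_mean, abs_diff), `structure_id`, `backend`.
#'   An error of class `escapist_unscorable` is raised when no pair has a
#'   template entry (distinct from a genuine score of 0).
#' @export
pd_score <- function(structure, template, config = feature_config(),
                     backend = c("builtin", "external"),
                     params = solver_params(), potentials_fun = NULL,
                     first_chain_only = FALSE) {
  backend <- match.arg(backend)
  if (!identical(toupper(template$mode),
                 toupper(c(config$atom_p, config$atom_q)))) {
    abort(sprintf(
      "template atom mode (%s-%s) does not match config (%s-%s)",
      template$mode[1], template$mode[2], config$atom_p, config$atom_q
    ), "escapist_mode_mismatch")
  }
  if (first_chain_only) {
    ch <- structure$residues$chain[1]
    structure$atoms <- structure$atoms[structure$atoms$chain == ch, ]
    structure <- new_protein_structure(structure$id, structure$atoms)
  }
  pf <- potentials_fun %||% default_potentials_fun(backend, params)
  pots <- pf(structure)
  pairs <- consecutive_pairs(structure, config$ignore_nterm,
                             config$ignore_cterm)
  obs <- epd_observations(pots, pairs, config,
                          structure_id = structure$id)
  idx <- match(obs$key, template$entries$pair)
  cmp <- !is.na(idx)
  if (!any(cmp)) {
    abort(sprintf(
      "structure '%s': no consecutive pair has a template entry (%d pairs seen)",
      structure$id, nrow(pairs)
    ), "escapist_unscorable")
  }
  contributions <- data.frame(
    chain = obs$chain[cmp], n = obs$n[cmp], pair = obs$key[cmp],
    observed = obs$value[cmp],
    template_mean = template$entries$mean[idx[cmp]],
    stringsAsFactors = FALSE
  )
  contributions$abs_diff <- abs(contributions$observed -
                                  contributions$template_mean)
  structure(
    list(pdscore = mean(contributions$abs_diff),
         number_compared = nrow(contributions),
         contributions = contributions,
         structure_id = structure$id,
         backend = attr(pots, "backend") %||% backend),
    class = "pd_score"
  )
}

#' @export
print.pd_score <- function(x, ...) {
  cat(sprintf("<pd_score> '%s': PDscore %.3f kT/e over %d compared pair(s)\n",
              x$structure_id, x$pdscore, x$number_compared))
  invisible(x)
}

#' @describeIn learn_features score a structure against a learned template
#'   (the quality-assessment phase); equivalent to [pd_score()].
#' @param object an `epd_template`.
#' @param structure a `protein_structure` to score.
#' @param ... passed on to [pd_score()].
#' @export
predict.epd_template <- function(object, structure,
                                 config = feature_config(
                                   atom_p = object$mode[1],
                                   atom_q = object$mode[2]
                                 ), ...) {
  pd_score(structure, object, config = config, ...)
}

score_value <- function(x) {
  if (inherits(x, "pd_score")) x$pdscore else as.numeric(x)
}

#' Rank a native structure against its decoys
#'
#' Specificity is the fraction of decoys whose PDscore is strictly greater
#' than the native's; a decoy tying the native counts against it. The
#' native's rank is 1 when it beats every decoy.
#'
#' @param native a `pd_score` (or bare numeric score) for the native.
#' @param decoys named list (or numeric vector) of decoy scores.
#' @param target_id identifier for reporting.
#' @return a `decoy_evaluation`: list with `target_id`, `native_score`,
#'   `decoy_scores`, `specificity` in `[0, 1]`, `native_rank`.
#' @export
rank_decoys <- function(native, decoys, target_id = "target") {
  stopifnot(length(decoys) >= 1L)
  nat <- score_value(native)
  dec <- vapply(decoys, score_value, numeric(1))
  structure(
    list(target_id = target_id,
         native_score = native,
         decoy_scores = decoys,
         specificity = mean(dec > nat),
         native_rank = 1L + sum(dec <= nat)),
    class = "decoy_evaluation"
  )
}

#' @export
print.decoy_evaluation <- function(x, ...) {
  cat(sprintf(
    "<decoy_evaluation> '%s': native %.3f, %d decoy(s), specificity %.3f (native rank %d)\n",
    x$target_id, score_value(x$native_score), length(x$decoy_scores),
    x$specificity, x$native_rank
  ))
  invisible(x)
}

# Resolve the native/decoy files of one target directory. Supported layouts:
#   * native.pdb + any other *.pdb decoys (the generated-fixture layout);
#   * a "list" file whose first entry is the native;
#   * misfold pairs: correct.pdb + incorrect*.pdb (first incorrect taken).
target_layout <- function(dir) {
  pdbs <- list.files(dir, pattern = "\\.(pdb|pqr|ent)$", full.names = TRUE)
  listfile <- file.path(dir, "list")
  if (file.exists(file.path(dir, "correct.pdb"))) {
    native <- file.path(dir, "correct.pdb")
    inc <- sort(grep("incorrect", pdbs, value = TRUE))
    if (!length(inc)) {
      abort(sprintf("misfold target '%s' has no incorrect structure", dir),
            "escapist_io_error")
    }
    decoys <- inc[1]
  } else if (file.exists(file.path(dir, "native.pdb"))) {
    native <- file.path(dir, "native.pdb")
    decoys <- setdiff(pdbs, native)
  } else if (file.exists(listfile)) {
    entries <- trimws(readLines(listfile))
    entries <- entries[nzchar(entries)]
    paths <- file.path(dir, entries)
    native <- paths[1]
    decoys <- paths[-1]
  } else {
    abort(sprintf(
      "target '%s' has no native.pdb, correct.pdb or list file", dir
    ), "escapist_io_error")
  }
  if (!length(decoys)) {
    abort(sprintf("target '%s' contains no decoy structures", dir),
          "escapist_io_error")
  }
  list(native = native, decoys = decoys)
}

#' Evaluate a directory of decoy sets
#'
#' `root` contains one subdirectory per target in a Decoys-R-Us-like layout
#' (see Details). Every structure is scored with [pd_score()]; per target
#' the native-versus-decoy specificity is reported, and the aggregate is the
#' unweighted mean specificity across targets. Structures that fail to parse
#' or score are excluded from the specificity denominator with a warning.
#'
#' @details Per-target layouts recognized: `native.pdb` plus decoy `*.pdb`
#' files; a `list` file whose first entry names the native; or a misfold
#' pair `correct.pdb` / `incorrect*.pdb` (the first incorrect file is used).
#'
#' @param root directory of target subdirectories.
#' @param template an `epd_template`.
#' @param config a [feature_config()].
#' @inheritParams pd_score
#' @return a `decoy_set_evaluation`: list with `evaluations` (per-target
#'   `decoy_evaluation`s), `summary` (data frame `PDB`, `NRes`,
#'   `NStructures`, `NativeScore`, `Specificity`), `mean_specificity`,
#'   `n_failed`.
#' @export
evaluate_decoy_set <- function(root, template, config = feature_config(),
                               backend = c("builtin", "external"),
                               params = solver_params(),
                               potentials_fun = NULL) {
  backend <- match.arg(backend)
  if (!dir.exists(root)) {
    abort(sprintf("decoy root not found: %s", root), "escapist_io_error")
  }
  targets <- list.dirs(root, recursive = FALSE)
  if (!length(targets)) {
    abort(sprintf("no target directories under %s", root),
          "escapist_io_error")
  }
  n_failed <- 0L
  evaluations <- list()
  rows <- list()
  for (dir in targets) {
    lay <- target_layout(dir)
    score_file <- function(path) {
      tryCatch(
        pd_score(parse_structure(path), template, config,
                 backend = backend, params = params,
                 potentials_fun = potentials_fun),
        escapist_error = function(e) {
          warning(sprintf("skipping '%s': %s", path, conditionMessage(e)),
                  call. = FALSE)
          n_failed <<- n_failed + 1L
          NULL
        }
      )
    }
    native <- score_file(lay$native)
    if (is.null(native)) next
    decoys <- Filter(Negate(is.null), lapply(lay$decoys, score_file))
    names(decoys) <- vapply(decoys, function(s) s$structure_id, character(1))
    if (!length(decoys)) next
    ev <- rank_decoys(native, decoys, target_id = basename(dir))
    evaluations[[basename(dir)]] <- ev
    nres <- nrow(parse_structure(lay$native)$residues)
    rows[[basename(dir)]] <- data.frame(
      PDB = basename(dir), NRes = nres,
      NStructures = length(decoys) + 1L,
      NativeScore = native$pdscore,
      Specificity = ev$specificity,
      stringsAsFactors = FALSE
    )
  }
  if (!length(evaluations)) {
    abort(sprintf("no target under %s could be scored", root),
          "escapist_unscorable")
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  structure(
    list(evaluations = evaluations, summary = summary_df,
         mean_specificity = mean(summary_df$Specificity),
         n_failed = n_failed),
    class = "decoy_set_evaluation"
  )
}

#' @export
print.decoy_set_evaluation <- function(x, ...) {
  cat(sprintf(
    "<decoy_set_evaluation> %d target(s), mean specificity %.3f (%d structure(s) skipped)\n",
    nrow(x$summary), x$mean_specificity, x$n_failed
  ))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Aggregate specificities computed from already-known scores
#'
#' Convenience path for re-deriving per-target specificities from score
#' columns (e.g. a published correct/incorrect score table) through the same
#' ranking rule used for full evaluations.
#'
#' @param native_scores numeric vector of native scores.
#' @param decoy_scores list of numeric vectors, one per target.
#' @param target_ids character vector of target names.
#' @return data frame `target`, `specificity`, plus attribute
#'   `mean_specificity`.
#' @export
specificity_from_scores <- function(native_scores, decoy_scores,
                                    target_ids = names(decoy_scores)) {
  stopifnot(length(native_scores) == length(decoy_scores))
  spec <- vapply(seq_along(native_scores), function(i) {
    rank_decoys(native_scores[i], decoy_scores[[i]],
                target_id = target_ids[i])$specificity
  }, numeric(1))
  out <- data.frame(target = target_ids, specificity = spec,
                    stringsAsFactors = FALSE)
  attr(out, "mean_specificity") <- mean(spec)
  out
}
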