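# The verification step: parse every candidate name back to a structure and
# emit the highest-ranked candidate whose structure is canonically equal to
# the input -- otherwise abstain.  A name that is wrong is never displayed.

#' Verify beam candidates against the input structure
#'
#' Each candidate is passed through a name-to-structure `parser`; a
#' candidate is *valid* if the parser produces any structure and *correct*
#' if that structure is canonically equal to the input.  The highest-ranked
#' correct candidate is emitted; if none is correct the result is an
#' abstention.  Parser failures count as invalid candidates, never as
#' errors.
#'
#' @param input_smiles The source structure (SMILES).
#' @param candidates A data.frame of candidates as returned by
#'   [translate_beam()] (columns `output`, `log_score`, `rank`), sorted by
#'   rank.
#' @param parser A function mapping a name to a SMILES string (default the
#'   package's [parse_iupac()]; any external name-to-structure program can
#'   be injected here).  For SMILES-producing models use `identity`.
#' @return A `nomtrans_verified` object: list with `input_smiles`,
#'   `emitted` (the chosen output string, or `NA` on abstention),
#'   `emitted_rank`, `abstained`, `n_valid`, `n_correct`, and the
#'   `candidates` data.frame gaining `valid`/`correct` columns.
#' @export
verify_candidates <- function(input_smiles, candidates,
                              parser = parse_iupac) {
  stopifnot(is.data.frame(candidates),
            all(c("output", "rank") %in% names(candidates)))
  if (is.unsorted(candidates$rank)) {
    stop("candidates must be sorted by rank")
  }
  input_can <- canonical_smiles(input_smiles)
  k <- nrow(candidates)
  valid <- logical(k)
  correct <- logical(k)
  for (i in seq_len(k)) {
    smi <- tryCatch(parser(candidates$output[i]), error = function(e) NA_character_)
    if (is.na(smi)) next
    can <- tryCatch(canonical_smiles(smi), error = function(e) NA_character_)
    if (is.na(can)) next
    valid[i] <- TRUE
    correct[i] <- can == input_can
  }
  candidates$valid <- valid
  candidates$correct <- correct
  emit <- which(correct)[1L]
  structure(list(
    input_smiles = input_smiles,
    emitted = if (length(emit) && !is.na(emit)) candidates$output[emit] else NA_character_,
    emitted_rank = if (length(emit) && !is.na(emit)) candidates$rank[emit] else NA_integer_,
    abstained = !any(correct),
    n_valid = sum(valid),
    n_correct = sum(correct),
    candidates = candidates
  ), class = "nomtrans_verified")
}

#' @export
print.nomtrans_verified <- function(x, ...) {
  if (x$abstained) {
    cat(sprintf("abstained for %s (%d valid, 0 correct of %d candidates)\n",
                x$input_smiles, x$n_valid, nrow(x$candidates)))
  } else {
    cat(sprintf("%s -> \"%s\" (rank %d; %d valid, %d correct of %d candidates)\n",
                x$input_smiles, x$emitted, x$emitted_rank, x$n_valid,
                x$n_correct, nrow(x$candidates)))
  }
  invisible(x)
}

#' Use a reverse-direction model as the name-to-structure parser
#'
#' Wraps a fitted `name2smiles` [nomtrans()] model as a parser function
#' suitable for [verify_candidates()]'s `parser` argument, closing the
#' translation loop with a second network instead of a rule-based parser.
#' Unlike [parse_iupac()], the result is itself statistical; this is meant
#' for closed-loop experiments, not as the verification ground truth.
#'
#' @param model A fitted `name2smiles` model.
#' @param lexicon Lexicon used to tokenize candidate names.
#' @return A function mapping an IUPAC name to a SMILES string.
#' @export
model_parser <- function(model, lexicon = default_lexicon()) {
  stopifnot(inherits(model, "nomtrans"))
  if (model$direction != "name2smiles") {
    stop("model_parser needs a name2smiles model")
  }
  function(name) {
    translate_beam(model, name, k = 1L, lexicon = lexicon)[[1]]$output[1L]
  }
}

#' Histograms of name multiplicity per molecule
#'
#' Tallies, over a batch of verified translations, how many beam candidates
#' were chemically valid and how many were round-trip correct.  A model
#' that has learned the nomenclature, not memorized it, produces several
#' correct names for many molecules (multiple parent choices, substituent
#' orderings).
#'
#' @param results List of `nomtrans_verified` objects.
#' @return List with integer tables `n_valid` and `n_correct` (names are
#'   counts 0..beam), each summing to `length(results)`.
#' @export
multiplicity_histogram <- function(results) {
  stopifnot(is.list(results))
  nv <- vapply(results, function(r) r$n_valid, 0L)
  nc <- vapply(results, function(r) r$n_correct, 0L)
  list(n_valid = table(nv), n_correct = table(nc))
}

#' Translate with optional verification
#'
#' The end-to-end prediction path: beam-search decoding followed by the
#' verification step.  With `verify = TRUE` (default) the returned `output`
#' is either a round-trip-correct translation or `NA` (abstention): a
#' wrong name is never emitted.
#'
#' @param object A fitted [nomtrans()] model.
#' @param newdata Character vector of source strings.
#' @param beam Beam width.
#' @param verify Run the verification step.
#' @param parser Name-to-structure function used by verification.  Default:
#'   [parse_iupac()] for `smiles2name` models, [canonical_smiles()] for
#'   `name2smiles` models (whose candidates are already SMILES, verified
#'   against the structure named by the input).
#' @param lexicon Lexicon for tokenization.
#' @param ... Unused.
#' @return A data.frame with one row per input: `input`, `output` (`NA` on
#'   abstention), `n_valid`, `n_correct`, `abstained`, `emitted_rank`.
#'   With `verify = FALSE`, the top beam candidate and its score.
#' @export
predict.nomtrans <- function(object, newdata, beam = 5L, verify = TRUE,
                             parser = NULL, lexicon = default_lexicon(), ...) {
  cands <- translate_beam(object, newdata, k = beam, lexicon = lexicon)
  if (!verify) {
    return(data.frame(
      input = newdata,
      output = vapply(cands, function(cc) cc$output[1L], ""),
      log_score = vapply(cands, function(cc) cc$log_score[1L], 0),
      stringsAsFactors = FALSE
    ))
  }
  if (object$direction == "smiles2name") {
    if (is.null(parser)) parser <- parse_iupac
    inputs_smiles <- newdata
  } else {
    if (is.null(parser)) parser <- canonical_smiles
    # the reference structure is the one named by the input
    inputs_smiles <- vapply(newdata, function(nm) parse_iupac(nm, lexicon), "",
                            USE.NAMES = FALSE)
  }
  ver <- mapply(verify_candidates, inputs_smiles, cands,
                MoreArgs = list(parser = parser), SIMPLIFY = FALSE)
  data.frame(
    input = newdata,
    output = vapply(ver, function(v) v$emitted, ""),
    n_valid = vapply(ver, function(v) v$n_valid, 0L),
    n_correct = vapply(ver, function(v) v$n_correct, 0L),
    abstained = vapply(ver, function(v) v$abstained, NA),
    emitted_rank = vapply(ver, function(v) v$emitted_rank, NA_integer_),
    stringsAsFactors = FALSE
  )
}
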