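# Evaluation protocols: exact-match accuracy per beam size, accuracy versus
# SMILES token length, length distributions, stereo-density subsetting, and
# representation-robustness harnesses.

#' Evaluate a model on a paired test set
#'
#' Runs beam-search translation plus verification at each requested beam
#' width and assembles one evaluation record per molecule: token lengths in
#' both notations, stereo counts, the stereo-density index `I = S/N`
#' (stereo units per SMILES token), and per-beam correctness.  A molecule
#' counts as correct at beam `k` iff verification over the k candidates
#' emits a translation (which is then round-trip correct by construction);
#' abstentions count as incorrect.
#'
#' @param model A fitted [nomtrans()] model (direction `smiles2name`).
#' @param pairs data.frame with `smiles` and `name` columns (canonical
#'   SMILES).
#' @param beams Integer vector of beam widths to evaluate.
#' @param parser Name-to-structure function for verification.
#' @param lexicon Lexicon.
#' @return A data.frame of class `nomtrans_eval`: columns `smiles`, `name`,
#'   `smiles_len`, `iupac_len`, `n_stereocenters`, `stereo_density`,
#'   `correct_at_<k>` and `abstained_at_<k>` for each beam, and `n_valid`,
#'   `n_correct` at the largest beam.
#' @export
evaluate_model <- function(model, pairs, beams = c(1L, 3L, 5L),
                           parser = parse_iupac, lexicon = default_lexicon()) {
  stopifnot(inherits(model, "nomtrans"), is.data.frame(pairs),
            all(c("smiles", "name") %in% names(pairs)), nrow(pairs) > 0)
  beams <- sort(unique(as.integer(beams)))
  rec <- data.frame(
    smiles = pairs$smiles, name = pairs$name,
    smiles_len = smiles_length(pairs$smiles),
    iupac_len = vapply(pairs$name, function(x)
      length(tokenize_iupac(x, lexicon)$tokens), 0L, USE.NAMES = FALSE),
    n_stereocenters = count_stereocenters(pairs$smiles, canonicalize = FALSE),
    stringsAsFactors = FALSE
  )
  rec$stereo_density <- rec$n_stereocenters / rec$smiles_len
  last <- NULL
  for (k in beams) {
    cands <- translate_beam(model, pairs$smiles, k = k, lexicon = lexicon)
    ver <- mapply(verify_candidates, pairs$smiles, cands,
                  MoreArgs = list(parser = parser), SIMPLIFY = FALSE)
    rec[[paste0("correct_at_", k)]] <-
      vapply(ver, function(v) !v$abstained, NA)
    rec[[paste0("abstained_at_", k)]] <-
      vapply(ver, function(v) v$abstained, NA)
    last <- ver
  }
  rec$n_valid <- vapply(last, function(v) v$n_valid, 0L)
  rec$n_correct <- vapply(last, function(v) v$n_correct, 0L)
  attr(rec, "beams") <- beams
  attr(rec, "verified") <- last
  class(rec) <- c("nomtrans_eval", "data.frame")
  rec
}

#' Exact-match accuracy at a beam width
#'
#' Correct translations divided by total molecules; abstentions count as
#' incorrect.
#'
#' @param records A [evaluate_model()] result.
#' @param beam Beam width (must have been evaluated).
#' @return A fraction in `[0, 1]`.
#' @export
exact_match_accuracy <- function(records, beam) {
  if (!nrow(records)) stop("no evaluation records")
  col <- paste0("correct_at_", beam)
  if (!col %in% names(records)) {
    stop("records were not evaluated at beam ", beam)
  }
  mean(records[[col]])
}

#' SMILES-length bin grid for the applicability-domain analysis
#'
#' Lengths 3 to 10 in steps of 1, 10 to 100 in steps of 5, and 100 to 300
#' in steps of 10, with the duplicated seam values (10, 100) removed: 46
#' distinct bins from 3 to 300.
#'
#' @return Integer vector of bin centres.
#' @export
length_bins <- function() {
  unique(c(3:10, seq(10L, 100L, 5L), seq(100L, 300L, 10L)))
}

#' Accuracy by SMILES token length
#'
#' Records are assigned to the nearest length bin (ties toward the shorter
#' bin), at most `cap` records per bin in input order; empty bins are
#' absent from the table, never reported as zero.
#'
#' @param records A [evaluate_model()] result.
#' @param beam Beam width.
#' @param bins Length grid (default [length_bins()]).
#' @param cap Per-bin sample cap.
#' @return data.frame with `bin`, `n`, `accuracy`, sorted by bin.
#' @export
accuracy_by_length <- function(records, beam, bins = length_bins(),
                               cap = 1000L) {
  col <- paste0("correct_at_", beam)
  if (!col %in% names(records)) stop("records were not evaluated at beam ", beam)
  idx <- vapply(records$smiles_len, function(l) which.min(abs(bins - l)), 0L)
  out <- list()
  for (b in sort(unique(idx))) {
    rows <- which(idx == b)
    rows <- rows[seq_len(min(length(rows), cap))]
    out[[length(out) + 1L]] <- data.frame(
      bin = bins[b], n = length(rows), accuracy = mean(records[[col]][rows]))
  }
  do.call(rbind, out)
}

#' Stereo-enriched evaluation subset
#'
#' Restricts records to a SMILES token-length window and keeps the `size`
#' records with the highest stereo-density index `I = S/N`, ties broken by
#' input order.
#'
#' @param records A data.frame carrying `smiles_len` and `stereo_density`.
#' @param window Inclusive token-length bounds (default the 10--60 token
#'   applicability window).
#' @param size Number of records to keep.
#' @return The subset, ordered by decreasing stereo density.
#' @export
stereo_enriched_subset <- function(records, window = c(10L, 60L), size) {
  stopifnot(all(c("smiles_len", "stereo_density") %in% names(records)))
  win <- records[records$smiles_len >= window[1] &
                 records$smiles_len <= window[2], , drop = FALSE]
  ord <- order(-win$stereo_density)  # stable: ties keep input order
  if (nrow(win) < size) {
    warning(sprintf("only %d records in the length window (requested %d)",
                    nrow(win), size))
    size <- nrow(win)
  }
  win[ord[seq_len(size)], , drop = FALSE]
}

#' Representation-robustness harness
#'
#' Re-evaluates a model after rewriting every input SMILES into an
#' equivalent but differently written form -- `"kekulized"` (explicit
#' alternating bonds) or `"augmented"` (non-canonical traversal) -- while
#' judging correctness against the original, untransformed structure.
#' Inputs whose transformation fails are excluded and counted.
#'
#' @param model A fitted `smiles2name` [nomtrans()] model.
#' @param pairs data.frame with `smiles` (canonical) and `name`.
#' @param mode `"kekulized"` or `"augmented"`.
#' @param beams Beam widths.
#' @param seed Seed for the augmented traversal choice.
#' @param parser,lexicon Passed to verification.
#' @return List with `accuracy` (named by beam), `n_excluded`, and the
#'   per-molecule `records` (evaluated on the transformed inputs, lengths
#'   measured on the untransformed canonical input).
#' @export
robustness_harness <- function(model, pairs, mode = c("kekulized", "augmented"),
                               beams = c(1L, 3L, 5L), seed = 1L,
                               parser = parse_iupac,
                               lexicon = default_lexicon()) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) stop("empty pair list")
  trans <- rep(NA_character_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    trans[i] <- tryCatch(
      if (mode == "kekulized") kekulize_input(pairs$smiles[i])
      else augment_smiles(pairs$smiles[i], seed = seed + i),
      error = function(e) NA_character_)
  }
  keep <- !is.na(trans)
  n_excluded <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  trans <- trans[keep]
  beams <- sort(unique(as.integer(beams)))
  rec <- data.frame(
    smiles = pairs$smiles, transformed = trans, name = pairs$name,
    smiles_len = smiles_length(pairs$smiles),   # untransformed length
    stringsAsFactors = FALSE
  )
  acc <- stats::setNames(numeric(length(beams)), paste0("beam_", beams))
  for (j in seq_along(beams)) {
    k <- beams[j]
    cands <- translate_beam(model, trans, k = k, lexicon = lexicon)
    ver <- mapply(verify_candidates, pairs$smiles, cands,
                  MoreArgs = list(parser = parser), SIMPLIFY = FALSE)
    rec[[paste0("correct_at_", k)]] <- vapply(ver, function(v) !v$abstained, NA)
    acc[j] <- mean(rec[[paste0("correct_at_", k)]])
  }
  list(accuracy = acc, n_excluded = n_excluded, records = rec)
}

#' Token-length distributions of a corpus
#'
#' Means and integer-binned histograms of the SMILES and IUPAC token
#' lengths.
#'
#' @param records A data.frame carrying `smiles_len` and `iupac_len`
#'   (e.g. from [evaluate_model()]), or a pairs data.frame with `smiles` /
#'   `name` columns, in which case lengths are computed.
#' @param lexicon Lexicon for name tokenization if lengths are computed.
#' @return List with `mean_smiles`, `mean_iupac`, `hist_smiles`,
#'   `hist_iupac` (tables over integer lengths; masses sum to the record
#'   count).
#' @export
length_distribution <- function(records, lexicon = default_lexicon()) {
  if (!nrow(records)) stop("no records")
  if (!all(c("smiles_len", "iupac_len") %in% names(records))) {
    stopifnot(all(c("smiles", "name") %in% names(records)))
    records$smiles_len <- smiles_length(records$smiles)
    records$iupac_len <- vapply(records$name, function(x)
      length(tokenize_iupac(x, lexicon)$tokens), 0L, USE.NAMES = FALSE)
  }
  list(
    mean_smiles = mean(records$smiles_len),
    mean_iupac = mean(records$iupac_len),
    hist_smiles = table(records$smiles_len),
    hist_iupac = table(records$iupac_len)
  )
}
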