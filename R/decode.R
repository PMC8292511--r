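# Decoding: greedy reference path and beam search.

.encode_src <- function(model, src, lexicon) {
  notation <- if (model$direction == "smiles2name") "SMILES" else "IUPAC"
  toks <- .tokenize_side(src, notation, lexicon)  # errors if untokenizable
  ids <- .encode_tokens(toks, model$src_vocab)
  if (any(ids == 3L)) {
    stop("source contains a token outside the model vocabulary: ",
         toks[which(ids == 3L)[1]])
  }
  c(ids, 2L)  # terminal <eos>, as in training
}

#' Beam-search translation
#'
#' Decodes each source string with beam search of width `k`, returning up
#' to `k` candidates per input sorted by total log-probability (no length
#' normalization; ties broken toward the lower token id, so decoding is
#' deterministic).  With `k = 1` the single candidate equals greedy
#' decoding.  Untokenizable sources are rejected before decoding.
#'
#' @param model A fitted [nomtrans()] model.
#' @param src Character vector of source strings (SMILES or names,
#'   matching the model direction).
#' @param k Beam width (>= 1).
#' @param lexicon Lexicon for tokenization.
#' @return A list (one element per input) of data.frames with columns
#'   `output`, `log_score`, `rank` (0 = best), `finished`.
#' @export
translate_beam <- function(model, src, k = 5L, lexicon = default_lexicon()) {
  stopifnot(inherits(model, "nomtrans"), k >= 1L)
  src_ids <- lapply(src, .encode_src, model = model, lexicon = lexicon)
  res <- .tf_beam(model$params, model$ccfg, src_ids, as.integer(k),
                  model$ccfg$max_len)
  lapply(res, function(r) {
    out <- vapply(r$ids, function(ids) {
      ids <- ids[ids != 2L]  # strip <eos>
      detokenize(.decode_ids(ids, model$tgt_vocab))
    }, "")
    data.frame(output = out, log_score = r$log_score,
               rank = seq_along(out) - 1L, finished = r$finished,
               stringsAsFactors = FALSE)
  })
}

#' Greedy decoding (reference implementation)
#'
#' Step-by-step argmax decoding implemented independently of the beam
#' search code path; used to check the beam-1 equivalence property.
#'
#' @inheritParams translate_beam
#' @return Character vector of decoded outputs.
#' @export
translate_greedy <- function(model, src, lexicon = default_lexicon()) {
  stopifnot(inherits(model, "nomtrans"))
  vapply(src, function(s) {
    ids <- .encode_src(model, s, lexicon)
    prefix <- 1L  # <bos>
    out <- integer(0)
    for (step in seq_len(model$ccfg$max_len)) {
      lp <- .tf_logprobs(model$params, model$ccfg, ids, prefix)
      lp[1:2] <- -Inf  # never emit <pad>/<bos>
      nxt <- which.max(lp) - 1L  # ties resolve to the lower id
      if (nxt == 2L) break
      out <- c(out, nxt)
      prefix <- c(prefix, nxt)
    }
    detokenize(.decode_ids(out, model$tgt_vocab))
  }, "", USE.NAMES = FALSE)
}

#' Exhaustive top-k decoding oracle
#'
#' Enumerates every output sequence up to `max_len` tokens and scores it by
#' total log-probability under the model, returning the top `k`.  Only
#' feasible for toy vocabularies and lengths; serves as the brute-force
#' oracle for beam-search tests.
#'
#' @inheritParams translate_beam
#' @param src_ids Integer vector of 0-based source token ids.
#' @param max_len Maximum output length (excluding the end token).
#' @return data.frame with `ids` (list-column of integer vectors, without
#'   the end token) and `log_score`, sorted by decreasing score.
#' @export
enumerate_topk <- function(model, src_ids, k = 5L, max_len = 4L) {
  stopifnot(inherits(model, "nomtrans"))
  Vt <- model$ccfg$vocab_tgt
  results <- list()
  rec <- function(prefix, score) {
    lp <- .tf_logprobs(model$params, model$ccfg, src_ids, c(1L, prefix))
    # every sequence may terminate here
    results[[length(results) + 1L]] <<- list(ids = prefix, log_score = score + lp[3])
    if (length(prefix) < max_len) {
      for (v in seq(4L, Vt) - 1L) rec(c(prefix, v), score + lp[v + 1L])
    }
  }
  rec(integer(0), 0)
  sc <- vapply(results, `[[`, 0, "log_score")
  ord <- order(-sc)
  top <- results[ord[seq_len(min(k, length(results)))]]
  data.frame(
    ids = I(lapply(top, `[[`, "ids")),
    log_score = vapply(top, `[[`, 0, "log_score")
  )
}
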