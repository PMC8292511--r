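# Transformer model objects: configuration, vocabulary, fitting, methods.

.SPECIALS <- c("<pad>", "<bos>", "<eos>", "<unk>")

#' Transformer hyperparameter configuration
#'
#' Two presets are provided.  `"full"` is the full-scale architecture used
#' for PubChem-scale training: 6 encoder and 6 decoder layers, 8 attention
#' heads, attention dimension 512 and feed-forward dimension 2048.
#' `"desk"` is a small configuration (2+2 layers, 4 heads, d_model 128,
#' d_ff 256) that trains on a CPU in minutes and is used throughout the
#' package's tests and examples.
#'
#' @param preset `"desk"` or `"full"`.
#' @param n_encoder_layers,n_decoder_layers,n_heads,d_model,d_ff,max_len,dropout
#'   Individual overrides.
#' @return A `nomtrans_config` object.
#' @export
#' @examples
#' model_config("full")$d_model   # 512
model_config <- function(preset = c("desk", "full"),
                         n_encoder_layers = NULL, n_decoder_layers = NULL,
                         n_heads = NULL, d_model = NULL, d_ff = NULL,
                         max_len = NULL, dropout = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") {
    list(n_encoder_layers = 6L, n_decoder_layers = 6L, n_heads = 8L,
         d_model = 512L, d_ff = 2048L, max_len = 320L, dropout = 0.1)
  } else {
    list(n_encoder_layers = 2L, n_decoder_layers = 2L, n_heads = 4L,
         d_model = 128L, d_ff = 256L, max_len = 64L, dropout = 0.1)
  }
  ov <- list(n_encoder_layers = n_encoder_layers,
             n_decoder_layers = n_decoder_layers, n_heads = n_heads,
             d_model = d_model, d_ff = d_ff, max_len = max_len,
             dropout = dropout)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) cfg[[nm]] <- ov[[nm]]
  cfg[names(cfg) != "dropout"] <- lapply(cfg[names(cfg) != "dropout"], as.integer)
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("invalid configuration: d_model (", cfg$d_model,
         ") is not divisible by n_heads (", cfg$n_heads, ")")
  }
  cfg$preset <- preset
  structure(cfg, class = "nomtrans_config")
}

#' @export
print.nomtrans_config <- function(x, ...) {
  cat(sprintf(
    "Transformer config (%s): %d+%d layers, %d heads, d_model %d, d_ff %d, max_len %d, dropout %.2f\n",
    x$preset, x$n_encoder_layers, x$n_decoder_layers, x$n_heads, x$d_model,
    x$d_ff, x$max_len, x$dropout))
  invisible(x)
}

#' Optimization settings for [nomtrans()]
#'
#' Adam with the inverse-square-root warmup schedule and label smoothing,
#' the original Transformer training recipe.  A fixed seed gives an
#' identical parameter trajectory on the same backend.
#'
#' @param epochs Passes over the training pairs.
#' @param batch_size Examples per optimization step.
#' @param lr_mult Multiplier on the schedule `d_model^-0.5 *
#'   min(step^-0.5, step * warmup^-1.5)`.
#' @param warmup_steps Warmup length in steps.
#' @param label_smoothing Smoothing mass spread uniformly over the
#'   vocabulary (0 disables).
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `nomtrans_training` object.
#' @export
training_config <- function(epochs = 50L, batch_size = 64L, lr_mult = 0.5,
                            warmup_steps = 400L, label_smoothing = 0.1,
                            clip_norm = 1.0, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, warmup_steps >= 1,
            label_smoothing >= 0, label_smoothing < 1, clip_norm >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_mult = lr_mult,
                 warmup_steps = as.integer(warmup_steps),
                 label_smoothing = label_smoothing, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "nomtrans_training")
}

# vocabulary is fixed by the lexicon, not the corpus: specials, then the
# side's token inventory in lexicon order
.make_vocab <- function(lexicon, notation) {
  toks <- if (notation == "SMILES") lexicon$smiles_charset else lexicon$iupac$token
  c(.SPECIALS, toks)
}

# 0-based ids for the C++ side
.encode_tokens <- function(tokens, vocab) {
  id <- match(tokens, vocab)
  id[is.na(id)] <- 4L  # <unk>
  id - 1L
}
.decode_ids <- function(ids, vocab) vocab[ids + 1L]

.tokenize_side <- function(x, notation, lexicon) {
  if (notation == "SMILES") tokenize_smiles(x, lexicon)$tokens
  else tokenize_iupac(x, lexicon)$tokens
}

#' Fit a notation-translation Transformer
#'
#' Trains an encoder-decoder Transformer on paired (SMILES, IUPAC name)
#' data in the requested direction.  The two directions are independent
#' models with no weight sharing.  Pairs are tokenized with the lexicon
#' (character-level SMILES, rule-based IUPAC); pairs exceeding the
#' configured `max_len` are skipped and counted.
#'
#' @param pairs A data.frame with columns `smiles` and `name`, e.g. from
#'   [generate_pairs()] or [read_pairs()]; must already be tokenizable
#'   (see [screen_corpus()]).
#' @param direction `"smiles2name"` (structure to name) or `"name2smiles"`.
#' @param config A [model_config()].
#' @param training A [training_config()].
#' @param lexicon A [read_lexicon()] lexicon.
#' @param quiet Suppress the progress message.
#' @return An object of class `nomtrans`: the trained model handle with
#'   parameters, vocabularies, configs, the per-step `loss_trace` and the
#'   skipped-pair count.  Methods: [print()], [summary()], [coef()],
#'   [plot()] (loss trace), [predict()] (translation with optional beam
#'   search and verification).
#' @seealso [translate_beam()], [verify_candidates()], [nomtrans_update()]
#' @export
nomtrans <- function(pairs, direction = c("smiles2name", "name2smiles"),
                     config = model_config("desk"),
                     training = training_config(),
                     lexicon = default_lexicon(), quiet = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "nomtrans_config"),
            inherits(training, "nomtrans_training"),
            is.data.frame(pairs), all(c("smiles", "name") %in% names(pairs)))
  if (!nrow(pairs)) stop("cannot train on an empty corpus")
  scr <- screen_corpus(pairs, lexicon)
  if (scr$report$n_kept < nrow(pairs)) {
    stop(sprintf(
      "%d of %d pairs are not tokenizable; screen the corpus with screen_corpus() first",
      nrow(pairs) - scr$report$n_kept, nrow(pairs)))
  }

  src_not <- if (direction == "smiles2name") "SMILES" else "IUPAC"
  tgt_not <- if (direction == "smiles2name") "IUPAC" else "SMILES"
  src_vocab <- .make_vocab(lexicon, src_not)
  tgt_vocab <- .make_vocab(lexicon, tgt_not)

  src_col <- if (src_not == "SMILES") pairs$smiles else pairs$name
  tgt_col <- if (tgt_not == "SMILES") pairs$smiles else pairs$name
  # source sequences carry a terminal <eos>: its position is a sharp
  # length anchor for cross-attention (locants and stems depend on it)
  src_ids <- lapply(src_col, function(x)
    c(.encode_tokens(.tokenize_side(x, src_not, lexicon), src_vocab), 2L))
  tgt_ids <- lapply(tgt_col, function(x)
    c(1L, .encode_tokens(.tokenize_side(x, tgt_not, lexicon), tgt_vocab), 2L))

  ccfg <- unclass(config)
  ccfg$vocab_src <- length(src_vocab)
  ccfg$vocab_tgt <- length(tgt_vocab)

  if (!quiet) {
    message(sprintf(
      "training %s Transformer on %d pairs (%d epochs, batch %d, seed %d)",
      direction, length(src_ids), training$epochs, training$batch_size,
      training$seed))
  }
  init <- .tf_init(ccfg, training$seed)
  fit <- .tf_train(init, ccfg, src_ids, tgt_ids, unclass(training))

  structure(list(
    direction = direction,
    params = fit$params,
    config = config,
    ccfg = ccfg,
    training = training,
    src_vocab = src_vocab,
    tgt_vocab = tgt_vocab,
    lexicon_version = lexicon$version,
    loss_trace = fit$loss_trace,
    skipped = fit$skipped,
    steps = fit$steps,
    n_pairs = length(src_ids)
  ), class = "nomtrans")
}

#' Continue training a fitted model
#'
#' Runs additional epochs from the current parameters (the optimizer state
#' restarts, the learning-rate schedule resumes from the recorded step), so
#' long runs can be checkpointed and resumed.
#'
#' @param object A fitted [nomtrans()] model.
#' @param epochs Additional epochs.
#' @param pairs Training pairs (defaults must be supplied again; the model
#'   object does not retain the corpus).
#' @param quiet Suppress the progress message.
#' @return The updated `nomtrans` object.
#' @export
nomtrans_update <- function(object, pairs, epochs = 10L, quiet = FALSE) {
  stopifnot(inherits(object, "nomtrans"))
  lexicon <- default_lexicon()
  src_not <- if (object$direction == "smiles2name") "SMILES" else "IUPAC"
  tgt_not <- if (object$direction == "smiles2name") "IUPAC" else "SMILES"
  src_col <- if (src_not == "SMILES") pairs$smiles else pairs$name
  tgt_col <- if (tgt_not == "SMILES") pairs$smiles else pairs$name
  src_ids <- lapply(src_col, function(x)
    c(.encode_tokens(.tokenize_side(x, src_not, lexicon), object$src_vocab), 2L))
  tgt_ids <- lapply(tgt_col, function(x)
    c(1L, .encode_tokens(.tokenize_side(x, tgt_not, lexicon), object$tgt_vocab), 2L))
  tcfg <- unclass(object$training)
  tcfg$epochs <- as.integer(epochs)
  tcfg$step_offset <- object$steps
  if (!quiet) message(sprintf("resuming training for %d epochs from step %d",
                              epochs, object$steps))
  fit <- .tf_train(object$params, object$ccfg, src_ids, tgt_ids, tcfg)
  object$params <- fit$params
  object$loss_trace <- c(object$loss_trace, fit$loss_trace)
  object$steps <- fit$steps
  object
}

.n_params <- function(object) {
  sum(vapply(object$params, length, 0L))
}

#' @export
print.nomtrans <- function(x, ...) {
  cat(sprintf("nomtrans Transformer (%s)\n", x$direction))
  cat(sprintf("  %d+%d layers, %d heads, d_model %d, d_ff %d -- %s parameters\n",
              x$config$n_encoder_layers, x$config$n_decoder_layers,
              x$config$n_heads, x$config$d_model, x$config$d_ff,
              format(.n_params(x), big.mark = ",")))
  cat(sprintf("  trained %d steps on %d pairs (lexicon %s); final loss %.4f\n",
              x$steps, x$n_pairs, x$lexicon_version,
              utils::tail(x$loss_trace, 1)))
  if (x$skipped > 0) cat(sprintf("  %d pairs skipped (exceeded max_len)\n", x$skipped))
  invisible(x)
}

#' @export
summary.nomtrans <- function(object, ...) {
  lt <- object$loss_trace
  out <- list(
    direction = object$direction,
    n_parameters = .n_params(object),
    n_pairs = object$n_pairs,
    steps = object$steps,
    skipped = object$skipped,
    loss_first = lt[1],
    loss_final = utils::tail(lt, 1),
    loss_min = min(lt),
    src_vocab = length(object$src_vocab),
    tgt_vocab = length(object$tgt_vocab)
  )
  class(out) <- "summary.nomtrans"
  out
}

#' @export
print.summary.nomtrans <- function(x, ...) {
  cat(sprintf("nomtrans %s model: %s parameters, vocabularies %d -> %d\n",
              x$direction, format(x$n_parameters, big.mark = ","),
              x$src_vocab, x$tgt_vocab))
  cat(sprintf("  %d training steps over %d pairs (%d skipped)\n",
              x$steps, x$n_pairs, x$skipped))
  cat(sprintf("  loss: %.4f (first step) -> %.4f (final), min %.4f\n",
              x$loss_first, x$loss_final, x$loss_min))
  invisible(x)
}

#' @export
coef.nomtrans <- function(object, ...) object$params

#' @export
plot.nomtrans <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "optimization step", ylab = "smoothed cross-entropy",
       main = sprintf("training loss (%s)", x$direction), ...)
  invisible(x)
}
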