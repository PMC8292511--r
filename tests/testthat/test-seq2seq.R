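test_that("configuration presets and divisibility constraints hold", {
  pc <- model_config("full")
  expect_equal(pc$n_encoder_layers, 6L)
  expect_equal(pc$n_decoder_layers, 6L)
  expect_equal(pc$n_heads, 8L)
  expect_equal(pc$d_model, 512L)
  expect_equal(pc$d_ff, 2048L)
  dc <- model_config("desk")
  expect_equal(dc$d_model %% dc$n_heads, 0L)
  expect_error(model_config("desk", n_heads = 7, d_model = 512),
               "not divisible")
})

test_that("a model builds with a deterministic parameter count", {
  cfg <- list(n_encoder_layers = 1L, n_decoder_layers = 1L, n_heads = 2L,
              d_model = 16L, d_ff = 32L, max_len = 8L, dropout = 0,
              vocab_src = 10L, vocab_tgt = 12L)
  p1 <- nomtrans:::.tf_init(cfg, 1L)
  p2 <- nomtrans:::.tf_init(cfg, 1L)
  expect_identical(p1, p2)
  count <- sum(vapply(p1, length, 0L))
  # embeddings + output head + 1 enc layer + 1 dec layer, all biases and
  # layernorm gains/shifts included
  attn <- function() 4 * 16 * 16 + 4 * 16
  ln <- function() 2 * 16
  ffn <- function() 16 * 32 + 32 + 32 * 16 + 16
  expect_equal(count,
               (10 + 12) * 16 + 16 * 12 + 12 +
                 (attn() + ln() + ffn() + ln()) +
                 (2 * attn() + 3 * ln() + ffn()))
  p3 <- nomtrans:::.tf_init(cfg, 2L)
  expect_false(identical(p1$src_emb, p3$src_emb))
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- list(n_encoder_layers = 1L, n_decoder_layers = 1L, n_heads = 2L,
              d_model = 8L, d_ff = 16L, max_len = 10L, dropout = 0,
              vocab_src = 7L, vocab_tgt = 7L)
  P <- nomtrans:::.tf_init(cfg, 3L)
  src <- list(c(4L, 5L, 6L), c(5L, 4L))
  tgt <- list(c(1L, 6L, 4L, 2L), c(1L, 5L, 2L))
  lg <- nomtrans:::.tf_loss_grad(P, cfg, src, tgt, 0.1, TRUE)
  expect_gt(lg$loss, 0)
  expect_equal(lg$n_tokens, 5L)
  eps <- 2e-3
  set.seed(42)
  for (nm in sample(names(P), 10)) {
    i <- sample(length(P[[nm]]), 1)
    Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
    Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
    fd <- (nomtrans:::.tf_loss_grad(Pp, cfg, src, tgt, 0.1, FALSE)$loss -
           nomtrans:::.tf_loss_grad(Pm, cfg, src, tgt, 0.1, FALSE)$loss) / (2 * eps)
    an <- lg$grads[[nm]][i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 0.02)
  }
})

test_that("a one-pair corpus is memorized to near-zero loss", {
  pairs <- data.frame(smiles = "CCO", name = "ethanol")
  m <- nomtrans(pairs, "smiles2name",
                config = model_config("desk", n_encoder_layers = 1,
                                      n_decoder_layers = 1, n_heads = 2,
                                      d_model = 32, d_ff = 64, max_len = 16,
                                      dropout = 0),
                training = training_config(epochs = 250, batch_size = 1,
                                           lr_mult = 2, warmup_steps = 30,
                                           label_smoothing = 0, seed = 2),
                quiet = TRUE)
  expect_lt(tail(m$loss_trace, 1), 0.01)
  expect_identical(translate_greedy(m, "CCO"), "ethanol")
})

test_that("identical seed and config give an identical loss trace", {
  pairs <- data.frame(smiles = c("CCO", "CCC"),
                      name = c("ethanol", "propane"))
  run <- function() nomtrans(pairs, "smiles2name",
    config = model_config("desk", n_encoder_layers = 1, n_decoder_layers = 1,
                          n_heads = 2, d_model = 16, d_ff = 32, max_len = 16),
    training = training_config(epochs = 5, batch_size = 2, seed = 11),
    quiet = TRUE)
  expect_identical(run()$loss_trace, run()$loss_trace)
})

test_that("training rejects empty corpora and skips over-long pairs", {
  expect_error(nomtrans(data.frame(smiles = character(0),
                                   name = character(0)), "smiles2name"),
               "empty")
  pairs <- data.frame(
    smiles = c("CCO", strrep("C", 20)),
    name = c("ethanol", "icosane"))
  m <- nomtrans(pairs, "smiles2name",
                config = model_config("desk", n_encoder_layers = 1,
                                      n_decoder_layers = 1, n_heads = 2,
                                      d_model = 16, d_ff = 32, max_len = 8),
                training = training_config(epochs = 1, batch_size = 2, seed = 1),
                quiet = TRUE)
  expect_equal(m$skipped, 1L)
})

test_that("seed robustness: every seed memorizes the micro-corpus", {
  # the three-seed majority protocol at memorization scale
  ok <- vapply(1:3, function(s) {
    m <- toy_model(seed = s)
    all(translate_greedy(m, c("CCO", "CCC", "CO")) ==
          c("ethanol", "propane", "methanol"))
  }, NA)
  expect_gte(sum(ok), 2L)
})

test_that("beam-1 equals greedy decoding", {
  m <- toy_model()
  pairs <- small_corpus()
  srcs <- pairs$smiles[1:100]
  b1 <- vapply(translate_beam(m, srcs, k = 1), function(x) x$output[1], "")
  g <- translate_greedy(m, srcs)
  expect_identical(unname(b1), unname(g))
})

test_that("beam search matches the brute-force oracle on an enumerable model", {
  m <- toy_model()
  for (src in c("CCO", "CO")) {
    src_ids <- nomtrans:::.encode_src(m, src, default_lexicon())
    oracle <- enumerate_topk(m, src_ids, k = 5L, max_len = 3L)
    for (k in c(1L, 2L, 5L)) {
      bm <- nomtrans:::.tf_beam(m$params, m$ccfg, list(src_ids), k, 4L)[[1]]
      expect_equal(length(bm$ids), k)
      for (j in seq_len(k)) {
        expect_equal(bm$ids[[j]][-length(bm$ids[[j]])], oracle$ids[[j]],
                     info = sprintf("src=%s k=%d j=%d", src, k, j))
        expect_equal(bm$log_score[j], oracle$log_score[j], tolerance = 1e-5)
      }
    }
  }
})

test_that("beam candidates are sorted with contiguous ranks and scores improve with k", {
  m <- toy_model()
  srcs <- c("CCO", "CCC", "CO")
  best1 <- vapply(translate_beam(m, srcs, k = 1),
                  function(x) x$log_score[1], 0)
  for (k in c(2L, 5L)) {
    res <- translate_beam(m, srcs, k = k)
    for (i in seq_along(res)) {
      expect_lte(nrow(res[[i]]), k)
      expect_equal(res[[i]]$rank, seq_len(nrow(res[[i]])) - 1L)
      expect_true(all(diff(res[[i]]$log_score) <= 1e-6))
      # beam monotonicity: best score never degrades as k grows
      expect_gte(res[[i]]$log_score[1], best1[i] - 1e-5)
    }
  }
})

test_that("untokenizable sources are rejected before decoding", {
  m <- toy_model()
  expect_error(translate_beam(m, "CCq"), "charset|untokenizable")
})
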