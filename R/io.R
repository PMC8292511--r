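# File formats, manifests and the end-to-end pipeline.

#' Read a .smi file
#'
#' One record per line: the first whitespace-separated field is the SMILES,
#' an optional second field is an identifier.  Blank lines and `#` comments
#' are skipped; original line numbers are kept for error reporting.
#'
#' @param path Path to the file.
#' @return data.frame with columns `smiles`, `id` (NA when absent) and
#'   `line`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("zero records in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  data.frame(
    smiles = vapply(parts, `[[`, "", 1L),
    id = vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, ""),
    line = keep,
    stringsAsFactors = FALSE
  )
}

#' Read / write a paired corpus (TSV)
#'
#' Tab-separated `smiles<TAB>name`, one pair per line, `#` comments
#' allowed.  [write_pairs()] optionally writes a JSON manifest next to the
#' file with the generating spec, seed and an md5 checksum, so a corpus
#' can be reproduced and verified.
#'
#' @param path File path.
#' @return data.frame with `smiles` and `name`.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("zero records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed pair line: ", lines[which(bad)[1]])
  data.frame(smiles = vapply(parts, `[[`, "", 1L),
             name = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' @rdname read_pairs
#' @param pairs data.frame with `smiles` and `name` (e.g. from
#'   [generate_pairs()]).
#' @param manifest Write `<path>.manifest.json`.
#' @export
write_pairs <- function(pairs, path, manifest = TRUE) {
  writeLines(paste(pairs$smiles, pairs$name, sep = "\t"), path)
  if (manifest) {
    spec <- attr(pairs, "spec")
    info <- list(
      n_pairs = nrow(pairs),
      spec = if (!is.null(spec)) unclass(spec) else NULL,
      lexicon_version = default_lexicon()$version,
      md5 = unname(tools::md5sum(path)),
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(info, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Write / read translation results
#'
#' JSONL (one JSON object per molecule; abstentions serialize the output
#' as an explicit `null`) or TSV.  Reading back reconstructs the records.
#'
#' @param results data.frame from [predict.nomtrans()].
#' @param path File path.
#' @param format `"jsonl"` or `"tsv"`.
#' @export
write_results <- function(results, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(results))) {
      row <- as.list(results[i, , drop = FALSE])
      row <- lapply(row, function(v) if (is.na(v)) NULL else v)
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                  digits = NA), con)
    }
  } else {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      # null-serialized fields (abstentions) come back as NA
      x <- lapply(x, function(v) if (is.null(v)) NA else v)
      as.data.frame(x, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    out <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "",
                             quote = "")
  }
  out
}

#' Run the full pipeline
#'
#' Executes the stages generate -> screen -> train (or load) -> translate
#' -> verify -> evaluate, writing the corpus, per-molecule results, an
#' evaluation report and a run manifest into `outdir`.  Each stage can be
#' skipped through the config; a stage failure aborts with the stage name.
#'
#' @param config A named list:
#'   \describe{
#'     \item{outdir}{Output directory (created).}
#'     \item{generator}{Arguments for [generator_spec()] (or `NULL` with
#'       `pairs_file` set).}
#'     \item{pairs_file}{Optional TSV corpus to use instead of generating.}
#'     \item{holdout_fraction}{Held-out fraction (default 0.1).}
#'     \item{model}{Optional path to a saved model (skips training).}
#'     \item{train}{Logical: train if no model given (default TRUE).}
#'     \item{model_config, training}{Arguments for [model_config()] /
#'       [training_config()].}
#'     \item{beam}{Beam width for translation (default 5).}
#'     \item{verify}{Run verification (default TRUE).}
#'     \item{evaluate}{Run the evaluation protocols (default TRUE).}
#'     \item{seed}{Master seed (default 1).}
#'   }
#' @return Invisibly, a list with the manifest, the held-out results and
#'   the evaluation report.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- config
  if (is.null(cfg[["outdir"]])) stop("pipeline config needs an 'outdir'")
  dir.create(cfg[["outdir"]], showWarnings = FALSE, recursive = TRUE)
  seed <- cfg[["seed"]] %||0% 1L
  beam <- cfg[["beam"]] %||0% 5L

  pairs <- stage("generate", {
    if (!is.null(cfg[["pairs_file"]])) read_pairs(cfg[["pairs_file"]])
    else {
      gargs <- cfg[["generator"]] %||0% list()
      if (is.null(gargs$seed)) gargs$seed <- seed
      generate_pairs(do.call(generator_spec, gargs))
    }
  })
  scr <- stage("screen", screen_corpus(pairs))
  pairs <- scr$kept
  write_pairs(pairs, file.path(cfg[["outdir"]], "pairs.tsv"))

  hf <- cfg[["holdout_fraction"]] %||0% 0.1
  sp <- split_pairs(pairs, hf, seed + 1L)
  hold <- sp$holdout
  train <- sp$train

  model <- stage("train", {
    if (!is.null(cfg[["model"]])) readRDS(cfg[["model"]])
    else if (isFALSE(cfg[["train"]])) {
      stop("no model supplied and training is disabled")
    } else {
      mc <- do.call(model_config, cfg[["model_config"]] %||0% list())
      targs <- cfg[["training"]] %||0% list()
      if (is.null(targs$seed)) targs$seed <- seed
      tc <- do.call(training_config, targs)
      nomtrans(train, "smiles2name", mc, tc, quiet = TRUE)
    }
  })
  saveRDS(model, file.path(cfg[["outdir"]], "model.rds"))

  results <- stage("translate/verify", {
    predict(model, hold$smiles, beam = beam,
            verify = !isFALSE(cfg[["verify"]]))
  })
  write_results(results, file.path(cfg[["outdir"]], "results.jsonl"), "jsonl")

  report <- NULL
  if (!isFALSE(cfg[["evaluate"]])) {
    report <- stage("evaluate", {
      ev <- evaluate_model(model, hold, beams = beam)
      list(
        n_train = nrow(train), n_holdout = nrow(hold),
        screening = scr$report,
        accuracy = exact_match_accuracy(ev, beam),
        length_distribution = lapply(
          length_distribution(ev)[c("mean_smiles", "mean_iupac")], identity)
      )
    })
    jsonlite::write_json(report, file.path(cfg[["outdir"]], "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "outdir")],
    seed = seed,
    lexicon_version = default_lexicon()$version,
    package_version = as.character(utils::packageVersion("nomtrans")),
    checksums = as.list(tools::md5sum(
      file.path(cfg[["outdir"]], c("pairs.tsv", "results.jsonl")))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  names(manifest$checksums) <- c("pairs.tsv", "results.jsonl")
  jsonlite::write_json(manifest, file.path(cfg[["outdir"]], "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results, report = report,
                 model = model))
}

# default-or-value helper that treats NULL as missing
`%||0%` <- function(a, b) if (is.null(a)) b else a
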