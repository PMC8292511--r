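#' @useDynLib nomtrans, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.nomtrans_env <- new.env(parent = emptyenv())

# Characters accepted by the character-level SMILES tokenizer.  Covers the
# organic and aromatic subsets, bracket-atom syntax (two-letter elements,
# charges, chirality, explicit H), ring-bond digits incl. %nn, and bond /
# branch punctuation.  Anything outside this set is an untokenizable input.
.smiles_charset <- strsplit(paste0(
  "BCNOPSFIHKbcnopse",   # element letters: B C N O P S F I H K + aromatic + Se/Si letters
  "ailrgdtu",            # second letters: Cl Br Si Se As Te Li Na Mg Cu ...
  "0123456789",
  "()[]=#-+\\/@%.:*~$"
), "")[[1]]

#' Load an IUPAC token lexicon
#'
#' Reads a plain-text, tab-separated lexicon file (`token<TAB>class`, `#`
#' comments) into a `nomtrans_lexicon` object.  The lexicon carries the
#' curated IUPAC vocabulary -- parent-hydride stems, suffixes, substituent
#' prefixes, multiplying prefixes, stereo descriptors, locant digits,
#' punctuation and element-style symbols -- together with the SMILES
#' character set used by [tokenize_smiles()].
#'
#' @param path Path to a lexicon file.  The default loads the lexicon
#'   shipped with the package.
#' @return An object of class `nomtrans_lexicon`: a list with elements
#'   `iupac` (data.frame of `token`, `class`), `smiles_charset` (character
#'   vector of single characters) and `version` (string).
#' @export
#' @examples
#' lex <- default_lexicon()
#' table(lex$iupac$class)
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  version <- "unversioned"
  vline <- grep("^#\\s*version:", lines, value = TRUE)
  if (length(vline)) version <- trimws(sub("^#\\s*version:", "", vline[1]))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed lexicon line(s): ", paste(lines[bad], collapse = "; "))
  df <- data.frame(
    token = vapply(parts, `[[`, "", 1L),
    class = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(df$token))) stop("lexicon contains an empty token")
  key <- paste(df$token, df$class, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate lexicon entries: ",
         paste(unique(df$token[duplicated(key)]), collapse = ", "))
  }
  lex <- structure(
    list(iupac = df, smiles_charset = .smiles_charset, version = version),
    class = "nomtrans_lexicon"
  )
  lex$index <- .build_match_index(df$token)
  lex
}

# Group tokens by first character, longest first, for greedy matching.
.build_match_index <- function(tokens) {
  first <- substr(tokens, 1L, 1L)
  idx <- split(tokens, first)
  lapply(idx, function(v) v[order(-nchar(v), v)])
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  if (is.null(.nomtrans_env$lexicon)) {
    path <- system.file("extdata", "iupac_lexicon_v1.tsv", package = "nomtrans")
    .nomtrans_env$lexicon <- read_lexicon(path)
  }
  .nomtrans_env$lexicon
}

#' @export
print.nomtrans_lexicon <- function(x, ...) {
  cat("IUPAC token lexicon, version ", x$version, "\n", sep = "")
  cls <- table(x$iupac$class)
  cat("  ", nrow(x$iupac), " tokens in ", length(cls), " classes: ",
      paste(names(cls), cls, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  SMILES charset: ", length(x$smiles_charset), " characters\n", sep = "")
  invisible(x)
}

.new_token_seq <- function(notation, tokens, source) {
  structure(list(notation = notation, tokens = tokens, source = source),
            class = "nomtrans_tokens")
}

#' @export
print.nomtrans_tokens <- function(x, ...) {
  cat(x$notation, " token sequence (", length(x$tokens), " tokens): ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Tokenize a SMILES string
#'
#' Character-level SMILES tokenization: one token per character, in order,
#' so that concatenating the tokens reproduces the input exactly.  An
#' optional atom-level mode keeps bracket atoms and the two-letter halogens
#' `Cl`/`Br` as single tokens.
#'
#' @param s A single SMILES string.
#' @param lexicon A [read_lexicon()] object supplying the SMILES character
#'   set.
#' @param mode `"character"` (default) or `"atom"`.
#' @return A `nomtrans_tokens` object.
#' @export
#' @examples
#' tokenize_smiles("CCO")$tokens
#' length(tokenize_smiles("O=c1cc[nH]c(=O)[nH]1")$tokens)  # 20
tokenize_smiles <- function(s, lexicon = default_lexicon(),
                            mode = c("character", "atom")) {
  mode <- match.arg(mode)
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop("`s` must be a single SMILES string")
  }
  if (!nzchar(s)) stop("cannot tokenize an empty SMILES string")
  chars <- strsplit(s, "", fixed = FALSE)[[1]]
  out <- !(chars %in% lexicon$smiles_charset)
  if (any(out)) {
    i <- which(out)[1L]
    stop(sprintf("untokenizable SMILES: character '%s' at position %d is outside the SMILES charset",
                 chars[i], i))
  }
  if (mode == "character") {
    toks <- chars
  } else {
    toks <- regmatches(s, gregexpr("\\[[^]]*\\]|Cl|Br|%[0-9]{2}|.", s))[[1]]
  }
  .new_token_seq("SMILES", toks, s)
}

#' Tokenize an IUPAC name
#'
#' Rule-based segmentation of an IUPAC name into lexicon tokens using
#' greedy longest-match scanning with single-step backtracking at dead
#' ends.  Tokenization is deterministic for a fixed lexicon and lossless:
#' the concatenation of the returned tokens equals the input.  Names that
#' admit no complete segmentation (a fragment is absent from the lexicon)
#' are rejected with the longest tokenizable prefix reported.
#'
#' @param name A single IUPAC name.
#' @param lexicon A [read_lexicon()] lexicon.
#' @return A `nomtrans_tokens` object.
#' @export
#' @examples
#' tokenize_iupac("pyrimidine-2,4-diol")$tokens
tokenize_iupac <- function(name, lexicon = default_lexicon()) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("`name` must be a single IUPAC name")
  }
  if (!nzchar(name)) stop("cannot tokenize an empty IUPAC name")
  idx <- lexicon$index
  n <- nchar(name)
  tokens <- character(0)
  alts <- list()      # untried shorter alternatives for the previous token
  pos <- 1L
  farthest <- 1L
  repeat {
    if (pos > n) break
    cand <- idx[[substr(name, pos, pos)]]
    if (!is.null(cand)) {
      cand <- cand[substring(name, pos, pos + nchar(cand) - 1L) == cand]
    }
    if (is.null(cand) || !length(cand)) {
      # dead end: single-step backtrack to the previous choice point
      farthest <- max(farthest, pos)
      k <- length(tokens)
      if (k > 0L && length(alts[[k]])) {
        pos <- pos - nchar(tokens[k])
        nxt <- alts[[k]][1L]
        alts[[k]] <- alts[[k]][-1L]
        tokens[k] <- nxt
        pos <- pos + nchar(nxt)
        next
      }
      stop(sprintf(
        "untokenizable IUPAC name: no lexicon segmentation at position %d; longest tokenizable prefix is \"%s\"",
        farthest, substr(name, 1L, farthest - 1L)))
    }
    tokens <- c(tokens, cand[1L])
    alts[[length(tokens)]] <- cand[-1L]
    pos <- pos + nchar(cand[1L])
    farthest <- max(farthest, pos)
  }
  .new_token_seq("IUPAC", tokens, name)
}

#' Reassemble a token sequence into its source string
#'
#' The inverse of tokenization: concatenates tokens.  For every accepted
#' input, `detokenize(tokenize_*(x))` is `x` byte for byte.
#'
#' @param t A `nomtrans_tokens` object (or a bare character vector of
#'   tokens).
#' @return A single string.
#' @export
detokenize <- function(t) {
  if (inherits(t, "nomtrans_tokens")) t <- t$tokens
  paste(t, collapse = "")
}

#' Exhaustive segmentation check for an IUPAC name
#'
#' Dynamic-programming oracle: decides whether *any* segmentation of `name`
#' into lexicon tokens exists (not just the greedy one).  Used to audit the
#' greedy tokenizer for lexicon-ambiguity cases.
#'
#' @inheritParams tokenize_iupac
#' @return `TRUE` if a complete segmentation exists.
#' @export
segmentable <- function(name, lexicon = default_lexicon()) {
  if (!nzchar(name)) return(FALSE)
  n <- nchar(name)
  reach <- logical(n + 1L)
  reach[1L] <- TRUE
  for (i in seq_len(n)) {
    if (!reach[i]) next
    cand <- lexicon$index[[substr(name, i, i)]]
    if (is.null(cand)) next
    hit <- substring(name, i, i + nchar(cand) - 1L) == cand
    reach[i + nchar(cand[hit])] <- TRUE
  }
  reach[n + 1L]
}

#' Screen a paired corpus for tokenizability
#'
#' Keeps exactly the (SMILES, name) pairs where both sides tokenize under
#' the lexicon; molecules that cannot be tokenized are excluded, mirroring
#' the corpus-preparation rule used for training and test sets.
#'
#' @param pairs A data.frame with columns `smiles` and `name`.
#' @param lexicon A [read_lexicon()] lexicon.
#' @return A list with `kept` (the surviving rows), and `report`: counts of
#'   inputs, keeps, rejections by cause (`n_rejected_smiles`,
#'   `n_rejected_name`), and the `coverage` fraction.
#' @export
screen_corpus <- function(pairs, lexicon = default_lexicon()) {
  stopifnot(is.data.frame(pairs), all(c("smiles", "name") %in% names(pairs)))
  ok_smi <- vapply(pairs$smiles, function(s) {
    !inherits(try(tokenize_smiles(s, lexicon), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
  ok_name <- vapply(pairs$name, function(x) {
    !inherits(try(tokenize_iupac(x, lexicon), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
  keep <- ok_smi & ok_name
  list(
    kept = pairs[keep, , drop = FALSE],
    report = list(
      n_input = nrow(pairs),
      n_kept = sum(keep),
      n_rejected_smiles = sum(!ok_smi),
      n_rejected_name = sum(!ok_name),
      coverage = if (nrow(pairs)) sum(keep) / nrow(pairs) else NA_real_
    )
  )
}
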