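# Canonicalization and structure-level utilities.  All structure identity
# decisions in the package go through one fixed canonicalizer (Open Babel's
# canonical SMILES writer, via ChemmineOB); stereo and isotope information
# participate in equality, so tautomers and stereoisomers are distinct.

#' Canonical SMILES
#'
#' Maps SMILES strings to canonical SMILES under the package's fixed
#' canonicalizer (Open Babel).  Vectorized; molecules are converted in one
#' batched call.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C1=CC=CC=C1"))
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  if (any(is.na(smiles) | !nzchar(smiles))) {
    stop("canonical_smiles: empty or NA SMILES at position ",
         which(is.na(smiles) | !nzchar(smiles))[1L])
  }
  # pass the element index as the molecule title so output lines can be
  # realigned even if Open Babel drops unparseable molecules
  src <- paste0(smiles, " m", seq_along(smiles), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(smiles))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    can <- vapply(parts, `[[`, "", 1L)
    ids <- as.integer(sub("^m", "", vapply(parts, function(p) {
      if (length(p) >= 2L) trimws(p[[2L]]) else ""
    }, "")))
    ok <- !is.na(ids) & ids >= 1L & ids <= length(smiles) & nzchar(can)
    res[ids[ok]] <- can[ok]
  }
  if (anyNA(res)) {
    i <- which(is.na(res))[1L]
    stop(sprintf("canonical_smiles: molecule %d (\"%s\") could not be parsed",
                 i, smiles[i]))
  }
  res
}

#' Canonical equality of two structures
#'
#' `TRUE` iff both SMILES map to the same canonical form under the one
#' fixed canonicalizer applied to both sides.  Unparseable input raises an
#' error naming the offending side.
#'
#' @param a,b SMILES strings (vectorized, recycled to common length).
#' @return Logical vector.
#' @export
#' @examples
#' canonical_equal("CCO", "OCC")                  # TRUE
#' canonical_equal("C1=CC=CC=C1", "c1ccccc1")     # TRUE
canonical_equal <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ca <- tryCatch(canonical_smiles(a), error = function(e) {
    stop("canonical_equal: left side: ", conditionMessage(e))
  })
  cb <- tryCatch(canonical_smiles(b), error = function(e) {
    stop("canonical_equal: right side: ", conditionMessage(e))
  })
  ca == cb
}

.obabel_convert <- function(smiles, extra_args) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".smi")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste0(smiles, " m", seq_along(smiles)), infile)
  status <- suppressWarnings(system2(
    "obabel", c(infile, "-osmi", "-O", outfile, extra_args),
    stdout = FALSE, stderr = FALSE
  ))
  if (!file.exists(outfile)) return(rep(NA_character_, length(smiles)))
  lines <- readLines(outfile, warn = FALSE)
  res <- rep(NA_character_, length(smiles))
  parts <- strsplit(lines, "[ \t]+")
  for (p in parts) {
    if (length(p) >= 2L && grepl("^m[0-9]+$", p[[2L]])) {
      res[as.integer(sub("^m", "", p[[2L]]))] <- p[[1L]]
    }
  }
  res
}

#' Kekulized SMILES
#'
#' Rewrites aromatic rings as alternating explicit single/double bonds.
#' The output contains no lowercase aromatic atom symbols and is
#' canonically equal to the input.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of kekulized SMILES.
#' @export
#' @examples
#' kekulize_input("c1ccccc1")
#' kekulize_input("CCO")   # fixpoint: nothing aromatic
kekulize_input <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  out <- .obabel_convert(smiles, "-xk")
  bad <- is.na(out) | grepl("[cnops]", gsub("\\[[^]]*\\]", "", out))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("kekulize_input: molecule %d (\"%s\") could not be kekulized",
                 i, smiles[i]))
  }
  out
}

# atom-level token pattern (bracket atoms, two-letter halogens, organic set)
.atom_regex <- "\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnops]"

.count_atoms <- function(s) {
  length(regmatches(s, gregexpr(.atom_regex, s))[[1]])
}

#' Non-canonical SMILES of the same molecule
#'
#' Produces an alternative (augmented) SMILES string for each input by
#' re-rooting Open Babel's traversal at a pseudo-randomly chosen atom.  The
#' output always parses to a molecule canonically equal to the input and
#' differs from the input string whenever the molecule admits any
#' alternative traversal.
#'
#' @param smiles Character vector of SMILES.
#' @param seed Integer seed controlling the root-atom choice; the function
#'   is a pure function of `(smiles, seed)`.
#' @return Character vector of augmented SMILES.
#' @export
#' @examples
#' augment_smiles("CCO", seed = 1)
augment_smiles <- function(smiles, seed = 1L) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  rng <- .lcg_new(seed)
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    na <- .count_atoms(s)
    if (na == 0L) stop(sprintf("augment_smiles: molecule %d (\"%s\") is unparseable", i, s))
    if (na == 1L) { out[i] <- s; next }
    roots <- .lcg_shuffle(rng, seq_len(na))
    res <- s
    for (r in roots) {
      cand <- .obabel_convert(s, paste0("-xf", r))
      if (!is.na(cand) && nzchar(cand) && cand != s) { res <- cand; break }
    }
    if (is.na(res)) stop(sprintf("augment_smiles: molecule %d (\"%s\") failed to convert", i, s))
    out[i] <- res
  }
  bad <- !canonical_equal(out, smiles)
  if (any(bad)) {
    stop("augment_smiles: traversal changed the molecule for input ",
         which(bad)[1L], " -- this is a bug")
  }
  out
}

# --- tiny deterministic generator (Lehmer / Park-Miller), independent of
# --- R's global RNG so package randomness never disturbs user code
.lcg_new <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- (as.numeric(seed) %% 2147483646) + 1
  e
}
.lcg_next <- function(rng) {
  rng$state <- (16807 * rng$state) %% 2147483647
  rng$state / 2147483647
}
.lcg_int <- function(rng, n) as.integer(floor(.lcg_next(rng) * n)) + 1L
.lcg_shuffle <- function(rng, x) {
  n <- length(x)
  if (n < 2L) return(x)
  for (i in seq_len(n - 1L)) {
    j <- i - 1L + .lcg_int(rng, n - i + 1L)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

#' Count stereo marks in a structure
#'
#' Counts stereo units as written in the canonical SMILES of the molecule:
#' tetrahedral chirality marks (`@`, `@@`) plus double bonds flanked by
#' directional bonds (`/`, `\`).  This is a string-level count on the
#' canonical form, which matches how the stereo-density protocols in this
#' package measure stereo content.
#'
#' @param smiles Character vector of SMILES.
#' @param canonicalize Canonicalize first (default `TRUE`).
#' @return Integer vector of stereo-unit counts.
#' @export
count_stereocenters <- function(smiles, canonicalize = TRUE) {
  if (!length(smiles)) return(integer(0))
  s <- if (canonicalize) canonical_smiles(smiles) else smiles
  tetra <- vapply(gregexpr("@@|@", s), function(m) sum(m > 0L), 0L)
  # lookahead so adjacent stereo bonds sharing a directional mark both count
  ez <- vapply(gregexpr("(?=[/\\\\][^=/\\\\]*=[^=/\\\\]*[/\\\\])", s, perl = TRUE),
               function(m) sum(m > 0L), 0L)
  tetra + ez
}

#' SMILES token length
#'
#' Number of tokens under the package's character-level SMILES tokenizer
#' (i.e. the string length).
#'
#' @param smiles Character vector of SMILES.
#' @return Integer vector.
#' @export
smiles_length <- function(smiles) nchar(smiles, type = "chars")
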