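# Synthetic (canonical SMILES, IUPAC name) pair generator.
#
# The nomenclature subclass is deliberately small and unambiguous: unbranched
# or methyl-branched acyclic chains C1..C20 carrying at most a few
# substituents whose correct names follow from table lookup plus
# deterministic lowest-locant rules.  Every batch is self-validated: each
# emitted name is parsed back to a structure by the package's name parser
# and must be canonically equal to the emitted SMILES.

.root_names <- c("meth", "eth", "prop", "but", "pent", "hex", "hept", "oct",
                 "non", "dec", "undec", "dodec", "tridec", "tetradec",
                 "pentadec", "hexadec", "heptadec", "octadec", "nonadec",
                 "icos")

.stem_ane <- function(n) paste0(.root_names[n], "ane")
.stem_an  <- function(n) paste0(.root_names[n], "an")
.root     <- function(n) .root_names[n]

.locs_str <- function(locs) paste(sort(locs), collapse = ",")

# chain SMILES builder used by the generator (structure route; the name
# route goes through the grammar and parse_iupac)
.gen_chain <- function(n, branches = list(), ene = NULL) {
  br <- vector("list", n)
  for (b in branches) br[[b$pos]] <- c(br[[b$pos]], b$smi)
  bonds <- rep("", max(n - 1L, 1L))
  if (!is.null(ene)) {
    bonds[ene$pos] <- "="
    if (!is.null(ene$stereo)) {
      bonds[ene$pos - 1L] <- "/"
      bonds[ene$pos + 1L] <- if (ene$stereo == "E") "/" else "\\"
    }
  }
  out <- character(0)
  for (i in seq_len(n)) {
    a <- "C"
    for (x in br[[i]]) a <- paste0(a, "(", x, ")")
    out <- c(out, a, if (i < n) bonds[i] else NULL)
  }
  paste(out, collapse = "")
}

# lexicographic comparison of equal-length sorted locant vectors
.locs_leq <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  TRUE
}
.canon_locs <- function(locs, n) {
  a <- sort(locs); b <- sort(n + 1L - locs)
  if (.locs_leq(a, b)) a else b
}
.is_canon <- function(locs, n) identical(sort(locs), .canon_locs(locs, n))

.halo <- list(chloro = "Cl", bromo = "Br")

# enumerate every distinct member of one family (n ranges over C1..C20)
.enumerate_family <- function(family) {
  acc <- new.env(parent = emptyenv())
  acc$name <- list(); acc$smiles <- list(); acc$stereo <- list()
  add <- function(name, smiles, stereo = FALSE) {
    k <- length(acc$name) + 1L
    acc$name[[k]] <- name; acc$smiles[[k]] <- smiles; acc$stereo[[k]] <- stereo
  }
  switch(family,
    "alkane" = for (n in 1:20) add(.stem_ane(n), .gen_chain(n)),
    "2-methylalkane" = for (n in 3:20) {
      add(paste0("2-methyl", .stem_ane(n)),
          .gen_chain(n, list(list(pos = 2L, smi = "C"))))
    },
    "alkan-1-ol" = for (n in 1:20) {
      nm <- if (n <= 2L) paste0(.stem_an(n), "ol") else paste0(.stem_an(n), "-1-ol")
      add(nm, .gen_chain(n, list(list(pos = 1L, smi = "O"))))
    },
    "alkan-2-one" = for (n in 3:20) {
      add(paste0(.stem_an(n), "-2-one"),
          .gen_chain(n, list(list(pos = 2L, smi = "=O"))))
    },
    "1-chloroalkane" = for (n in 1:20) {
      nm <- if (n <= 2L) paste0("chloro", .stem_ane(n)) else paste0("1-chloro", .stem_ane(n))
      add(nm, .gen_chain(n, list(list(pos = 1L, smi = "Cl"))))
    },
    "alk-2-ene-ez" = for (n in 4:20) for (st in c("E", "Z")) {
      add(sprintf("(%s)-%s-2-ene", st, .root(n)),
          .gen_chain(n, ene = list(pos = 2L, stereo = st)), stereo = TRUE)
    },
    "methylalkane" = for (n in 3:20) for (m in 2:floor((n + 1) / 2)) {
      add(sprintf("%d-methyl%s", m, .stem_ane(n)),
          .gen_chain(n, list(list(pos = m, smi = "C"))))
    },
    "alkanol" = for (n in 1:20) for (p in 1:ceiling(n / 2)) {
      nm <- if (n <= 2L) paste0(.stem_an(n), "ol")
            else sprintf("%s-%d-ol", .stem_an(n), p)
      add(nm, .gen_chain(n, list(list(pos = p, smi = "O"))))
    },
    "alkanone" = for (n in 3:20) for (p in 2:floor((n + 1) / 2)) {
      add(sprintf("%s-%d-one", .stem_an(n), p),
          .gen_chain(n, list(list(pos = p, smi = "=O"))))
    },
    "chloroalkane" = ,
    "bromoalkane" = {
      h <- sub("alkane$", "", family)
      for (n in 1:20) for (p in 1:ceiling(n / 2)) {
        nm <- if (n <= 2L) paste0(h, .stem_ane(n))
              else sprintf("%d-%s%s", p, h, .stem_ane(n))
        add(nm, .gen_chain(n, list(list(pos = p, smi = .halo[[h]]))))
      }
    },
    "alkene-ez" = for (n in 4:20) for (p in 2:floor(n / 2)) for (st in c("E", "Z")) {
      add(sprintf("(%s)-%s-%d-ene", st, .root(n), p),
          .gen_chain(n, ene = list(pos = p, stereo = st)), stereo = TRUE)
    },
    "alkenol-ez" = for (n in 4:20) for (p in 2:(n - 2)) for (st in c("E", "Z")) {
      add(sprintf("(%s)-%s-%d-en-1-ol", st, .root(n), p),
          .gen_chain(n, list(list(pos = 1L, smi = "O")),
                     ene = list(pos = p, stereo = st)), stereo = TRUE)
    },
    "alkanediol" = for (n in 2:20) {
      for (a in 1:(n - 1)) for (b in (a + 1):n) {
        if (!.is_canon(c(a, b), n)) next
        add(sprintf("%s-%s-diol", .stem_ane(n), .locs_str(c(a, b))),
            .gen_chain(n, list(list(pos = a, smi = "O"), list(pos = b, smi = "O"))))
      }
    },
    "dichloroalkane" = ,
    "dibromoalkane" = {
      h <- sub("^di(.*)alkane$", "\\1", family)
      for (n in 2:20) for (a in 1:n) for (b in a:n) {
        cap <- ifelse(c(a, b) %in% c(1L, n), 3L, 2L)
        if (a == b && cap[1] < 2L) next
        if (!.is_canon(c(a, b), n)) next
        add(sprintf("%s-di%s%s", .locs_str(c(a, b)), h, .stem_ane(n)),
            .gen_chain(n, list(list(pos = a, smi = .halo[[h]]),
                               list(pos = b, smi = .halo[[h]]))))
      }
    },
    "trichloroalkane" = ,
    "tribromoalkane" = {
      h <- sub("^tri(.*)alkane$", "\\1", family)
      for (n in 2:20) for (a in 1:n) for (b in a:n) for (cc in b:n) {
        locs <- c(a, b, cc)
        tab <- table(locs)
        cap <- ifelse(as.integer(names(tab)) %in% c(1L, n), 3L, 2L)
        if (any(tab > cap)) next
        if (!.is_canon(locs, n)) next
        add(sprintf("%s-tri%s%s", .locs_str(locs), h, .stem_ane(n)),
            .gen_chain(n, lapply(locs, function(p) list(pos = p, smi = .halo[[h]]))))
      }
    },
    "dimethylalkane" = for (n in 3:20) for (a in 2:(n - 1)) for (b in a:(n - 1)) {
      if (!.is_canon(c(a, b), n)) next
      add(sprintf("%s-dimethyl%s", .locs_str(c(a, b)), .stem_ane(n)),
          .gen_chain(n, list(list(pos = a, smi = "C"), list(pos = b, smi = "C"))))
    },
    "chloroalkanol" = ,
    "bromoalkanol" = {
      h <- sub("alkanol$", "", family)
      for (n in 2:20) for (p in 1:n) for (q in setdiff(1:n, p)) {
        # numbering: lowest locant to the principal group (-ol), then to
        # the halo prefix; keep only the canonical orientation
        d1 <- c(p, q); d2 <- c(n + 1L - p, n + 1L - q)
        if (!.locs_leq(d1, d2)) next
        add(sprintf("%d-%s%s-%d-ol", q, h, .stem_an(n), p),
            .gen_chain(n, list(list(pos = p, smi = "O"),
                               list(pos = q, smi = .halo[[h]]))))
      }
    },
    stop("unknown generator family: ", family)
  )
  if (!length(acc$name)) return(NULL)
  data.frame(family = family,
             name = unlist(acc$name), smiles = unlist(acc$smiles),
             stereo = unlist(acc$stereo), stringsAsFactors = FALSE)
}

# canonical SMILES are memoized per session: family enumerations reuse the
# same few thousand strings across generator calls
.canon_cache <- new.env(parent = emptyenv())
.canonical_cached <- function(smiles) {
  miss <- smiles[!vapply(smiles, exists, NA, envir = .canon_cache,
                         inherits = FALSE, USE.NAMES = FALSE)]
  miss <- unique(miss)
  if (length(miss)) {
    can <- canonical_smiles(miss)
    for (i in seq_along(miss)) assign(miss[i], can[i], envir = .canon_cache)
  }
  vapply(smiles, get, "", envir = .canon_cache, inherits = FALSE,
         USE.NAMES = FALSE)
}

.spec_families <- c("alkane", "2-methylalkane", "alkan-1-ol", "alkan-2-one",
                    "1-chloroalkane", "alk-2-ene-ez")
.extended_families <- c("alkane", "methylalkane", "alkanol", "alkanone",
                        "chloroalkane", "bromoalkane", "alkene-ez",
                        "alkenol-ez", "alkanediol", "dichloroalkane",
                        "dibromoalkane", "trichloroalkane", "tribromoalkane",
                        "dimethylalkane", "chloroalkanol", "bromoalkanol")

#' Available synthetic-pair families
#'
#' @return Character vector of family identifiers accepted by
#'   [generator_spec()].
#' @export
list_families <- function() unique(c(.spec_families, .extended_families))

#' Deterministic train/held-out split
#'
#' Shuffles pair rows with a seeded generator (independent of R's global
#' RNG) and holds out a fraction for evaluation.
#'
#' @param pairs A pairs data.frame.
#' @param holdout_fraction Fraction held out (at least one row).
#' @param seed Integer seed.
#' @return List with `train` and `holdout` data.frames.
#' @export
split_pairs <- function(pairs, holdout_fraction = 0.1, seed = 1L) {
  stopifnot(nrow(pairs) >= 2, holdout_fraction > 0, holdout_fraction < 1)
  rng <- .lcg_new(seed)
  idx <- .lcg_shuffle(rng, seq_len(nrow(pairs)))
  n_hold <- max(1L, round(nrow(pairs) * holdout_fraction))
  list(train = pairs[idx[-seq_len(n_hold)], , drop = FALSE],
       holdout = pairs[idx[seq_len(n_hold)], , drop = FALSE])
}

#' Specification for the synthetic pair generator
#'
#' A `nomtrans_genspec` fully determines a synthetic corpus: generation is
#' a pure function of the spec (same spec, same pairs).
#'
#' @param families Character vector of family identifiers (see
#'   [list_families()]).  The default is the full extended family set.
#' @param size Number of pairs to draw.
#' @param seed Integer seed for the draw.
#' @param length_window Inclusive bounds on the SMILES token count of kept
#'   members.
#' @param stereo_fraction Fraction of the corpus drawn from the
#'   stereo-bearing (E/Z) families.
#' @return A `nomtrans_genspec` object.
#' @export
generator_spec <- function(families = .extended_families, size = 5000L,
                           seed = 42L, length_window = c(1L, 60L),
                           stereo_fraction = 0.06) {
  stopifnot(length(families) >= 1L, size >= 1L,
            length(length_window) == 2L, length_window[1] <= length_window[2],
            stereo_fraction >= 0, stereo_fraction <= 1)
  bad <- setdiff(families, list_families())
  if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
  structure(list(families = families, size = as.integer(size),
                 seed = as.integer(seed),
                 length_window = as.integer(length_window),
                 stereo_fraction = stereo_fraction),
            class = "nomtrans_genspec")
}

#' @export
print.nomtrans_genspec <- function(x, ...) {
  cat("synthetic pair generator spec\n")
  cat("  families:", paste(x$families, collapse = ", "), "\n")
  cat(sprintf("  size %d, seed %d, SMILES length window [%d, %d], stereo fraction %.3f\n",
              x$size, x$seed, x$length_window[1], x$length_window[2],
              x$stereo_fraction))
  invisible(x)
}

#' Generate provably correct (canonical SMILES, IUPAC name) pairs
#'
#' Enumerates all distinct members of the requested families, canonicalizes
#' their structures, filters by the SMILES token-length window, and draws
#' `size` pairs without replacement (honouring `stereo_fraction`).  With
#' `self_validate = TRUE` (the default) every emitted name is parsed back
#' by [parse_iupac()] and checked canonically equal to its SMILES; any
#' failure is an error, so a returned corpus is round-trip correct by
#' construction.
#'
#' @param spec A [generator_spec()].
#' @param lexicon Lexicon used to assert that every name tokenizes.
#' @param self_validate Run the name->structure round-trip gate.
#' @return A data.frame with columns `smiles` (canonical), `name`,
#'   `family`, `stereo`; attribute `spec` carries the generating spec.
#' @export
#' @examples
#' \donttest{
#' pairs <- generate_pairs(generator_spec(families = "alkane", size = 5,
#'                                        seed = 1, stereo_fraction = 0))
#' pairs$name
#' }
generate_pairs <- function(spec, lexicon = default_lexicon(),
                           self_validate = TRUE) {
  stopifnot(inherits(spec, "nomtrans_genspec"))
  members <- do.call(rbind, lapply(unique(spec$families), .enumerate_family))
  members <- members[!duplicated(members$smiles), , drop = FALSE]
  members$smiles <- .canonical_cached(members$smiles)
  members <- members[!duplicated(members$smiles), , drop = FALSE]
  len <- smiles_length(members$smiles)
  members <- members[len >= spec$length_window[1] & len <= spec$length_window[2], ,
                     drop = FALSE]
  if (!nrow(members)) {
    stop("infeasible generator spec: the length window excludes every family member")
  }

  n_stereo <- round(spec$size * spec$stereo_fraction)
  n_plain <- spec$size - n_stereo
  pool_s <- which(members$stereo)
  pool_p <- which(!members$stereo)
  if (length(pool_s) < n_stereo || length(pool_p) < n_plain) {
    stop(sprintf(
      "infeasible generator spec: requested %d stereo + %d non-stereo pairs but only %d + %d distinct members exist",
      n_stereo, n_plain, length(pool_s), length(pool_p)))
  }
  rng <- .lcg_new(spec$seed)
  take <- c(.lcg_shuffle(rng, pool_s)[seq_len(n_stereo)],
            .lcg_shuffle(rng, pool_p)[seq_len(n_plain)])
  take <- .lcg_shuffle(rng, take)
  pairs <- members[take, , drop = FALSE]
  rownames(pairs) <- NULL

  # every emitted name must tokenize under the shipped lexicon
  for (nm in pairs$name) tokenize_iupac(nm, lexicon)

  if (self_validate) {
    back <- vapply(pairs$name, function(nm) parse_iupac(nm, lexicon), "",
                   USE.NAMES = FALSE)
    ok <- canonical_smiles(back) == pairs$smiles
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop(sprintf(
        "generator self-validation failed: \"%s\" parses to a structure different from %s",
        pairs$name[i], pairs$smiles[i]))
    }
  }
  attr(pairs, "spec") <- spec
  pairs
}
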