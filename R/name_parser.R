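# Rule-based IUPAC name -> structure parser.
#
# This is the package's built-in name-to-structure engine, playing the role
# an external nomenclature parser plays in the verification loop.  It covers
# substitutive nomenclature for acyclic parents (the synthetic-pair
# families: alkanes, alkanols, alkanones, haloalkanes, methyl-branched
# alkanes, (E/Z)-alkenes and -alkenols, diols and polysubstituted variants)
# plus the benzamide/anilino/carbamoyl vocabulary needed for multi-parent
# amide names.  It is deliberately not a general nomenclature engine: names
# outside its grammar raise an error, which the verification step treats as
# an invalid candidate.

.alkyl_roots <- c(
  meth = 1L, eth = 2L, prop = 3L, but = 4L, pent = 5L, hex = 6L, hept = 7L,
  oct = 8L, non = 9L, dec = 10L, undec = 11L, dodec = 12L, tridec = 13L,
  tetradec = 14L, pentadec = 15L, hexadec = 16L, heptadec = 17L,
  octadec = 18L, nonadec = 19L, icos = 20L
)

.mult_value <- c(di = 2L, tri = 3L, tetra = 4L)

# simple substituent groups: SMILES fragment, attachment atom first
.simple_groups <- list(
  chloro = "Cl", Chloro = "Cl", bromo = "Br", Bromo = "Br",
  fluoro = "F", iodo = "I",
  hydroxy = "O", Hydroxy = "O",
  methoxy = "OC", ethoxy = "OCC",
  amino = "N", Amino = "N",
  "tert-butyl" = "C(C)(C)C"
)

# chain-type substituent heads: number of carbons (acyl: C1 carries =O)
.chain_groups <- c(methyl = 1L, ethyl = 2L, propyl = 3L, butyl = 4L,
                   pentyl = 5L, hexyl = 6L)

.parser_state <- function(tokens) {
  e <- new.env(parent = emptyenv())
  e$t <- tokens
  e$i <- 1L
  e
}
.pk <- function(st, k = 0L) {
  j <- st$i + k
  if (j <= length(st$t)) st$t[[j]] else NA_character_
}
.adv <- function(st) { st$i <- st$i + 1L; invisible(st) }
.expect <- function(st, tok) {
  if (!identical(.pk(st), tok)) {
    stop(sprintf("name parser: expected \"%s\" at token %d, saw \"%s\"",
                 tok, st$i, .pk(st)))
  }
  .adv(st)
}
.skip_hyphen <- function(st) while (identical(.pk(st), "-")) .adv(st)

.is_digit <- function(tok) !is.na(tok) && grepl("^[0-9]$", tok)

# locant list: multi-digit numbers assembled from digit tokens, or "N"
.read_locants <- function(st) {
  locs <- character(0)
  repeat {
    if (.is_digit(.pk(st))) {
      num <- ""
      while (.is_digit(.pk(st))) { num <- paste0(num, .pk(st)); .adv(st) }
      locs <- c(locs, num)
    } else if (identical(.pk(st), "N")) {
      locs <- c(locs, "N"); .adv(st)
    } else break
    if (identical(.pk(st), ",")) .adv(st) else break
  }
  if (!length(locs)) stop("name parser: expected a locant at token ", st$i)
  locs
}

.frag <- function(smi, kind = "plain") list(smi = smi, kind = kind)

# ring-closure digits must be unique across nested rings within one name
.ring_env <- new.env(parent = emptyenv())
.ring_env$counter <- 1L
.next_ring_digit <- function() {
  d <- .ring_env$counter
  if (d > 9L) stop("name parser: too many rings in one name")
  .ring_env$counter <- d + 1L
  d
}

# benzene ring with substituents at locants (1 = attachment position);
# written aromatic, closure atom must be bare, so reflect if 6 is occupied
.render_ring <- function(subs) {
  pos <- vapply(subs, function(s) s$loc, 0L)
  if (any(pos == 6L)) {
    pos <- 8L - pos
    if (any(pos == 6L)) stop("name parser: unsupported ring substitution pattern")
  }
  if (anyDuplicated(pos) || any(pos < 2L | pos > 5L)) {
    stop("name parser: invalid benzene ring locants")
  }
  cells <- rep("c", 4L)
  for (k in seq_along(subs)) {
    cells[pos[k] - 1L] <- paste0("c(", subs[[k]]$frag$smi, ")")
  }
  d <- .next_ring_digit()
  paste0("c", d, paste(cells, collapse = ""), "c", d)
}

# saturated carbon chain fragment; subs: list of list(loc, frag); acyl
# puts =O on C1; returns SMILES with C1 as attachment atom
.render_chain <- function(n, subs, acyl = FALSE, ene = NULL) {
  atoms <- rep("C", n)
  branch <- rep("", n)
  if (acyl) branch[1L] <- "(=O)"
  for (s in subs) {
    if (is.na(s$loc) || s$loc < 1L || s$loc > n) {
      stop("name parser: chain locant out of range")
    }
    branch[s$loc] <- paste0(branch[s$loc],
                            if (s$frag$kind == "oxo") "(=O)"
                            else paste0("(", s$frag$smi, ")"))
  }
  bonds <- rep("", n - 1L + (n == 1L))
  if (!is.null(ene)) {
    p <- ene$pos
    if (p < 1L || p + 1L > n) stop("name parser: double-bond locant out of range")
    bonds[p] <- "="
    if (!is.null(ene$stereo)) {
      if (p < 2L || p + 2L > n) {
        stop("name parser: stereo descriptor on a terminal double bond")
      }
      bonds[p - 1L] <- "/"
      bonds[p + 1L] <- if (ene$stereo == "E") "/" else "\\"
    }
  }
  out <- character(0)
  for (i in seq_len(n)) {
    out <- c(out, paste0(atoms[i], branch[i]),
             if (i < n) bonds[i] else NULL)
  }
  paste(out, collapse = "")
}

# a parsed group token (possibly "tert"-composite); returns group id
.parse_group_token <- function(st, lexicon) {
  tok <- .pk(st)
  if (identical(tok, "tert")) {
    .adv(st); .expect(st, "-")
    if (!identical(.pk(st), "butyl")) {
      stop("name parser: only tert-butyl is supported among tert- groups")
    }
    .adv(st)
    return("tert-butyl")
  }
  .adv(st)
  tok
}

# build a substituent fragment from a head group id plus attached items
.build_substituent <- function(grp, items, stereo = NULL) {
  if (grp %in% names(.simple_groups)) {
    base <- .simple_groups[[grp]]
    if (grp %in% c("amino", "Amino")) {
      extra <- paste(vapply(items, function(s) s$frag$smi, ""), collapse = ")(")
      if (length(items)) base <- paste0("N(", extra, ")")
      return(.frag(base))
    }
    if (length(items)) stop("name parser: group '", grp, "' takes no substituents")
    return(.frag(base))
  }
  if (grp == "oxo") {
    if (length(items)) stop("name parser: oxo takes no substituents")
    return(.frag("", kind = "oxo"))
  }
  if (grp %in% names(.chain_groups)) {
    return(.frag(.render_chain(.chain_groups[[grp]], .int_locs(items))))
  }
  if (grp == "acetyl") {
    return(.frag(.render_chain(2L, .int_locs(items), acyl = TRUE)))
  }
  if (grp == "anilino") {
    return(.frag(paste0("N", .render_ring(.int_locs(items)))))
  }
  if (grp == "phenyl") {
    return(.frag(.render_ring(.int_locs(items))))
  }
  if (grp == "carbamoyl") {
    ext <- paste(vapply(items, function(s) s$frag$smi, ""), collapse = ")(")
    return(.frag(if (length(items)) paste0("C(=O)N(", ext, ")") else "C(=O)N"))
  }
  stop("name parser: unsupported substituent group '", grp, "'")
}

.int_locs <- function(items) {
  lapply(items, function(s) {
    loc <- suppressWarnings(as.integer(s$loc))
    if (is.na(loc)) stop("name parser: a numeric locant is required here")
    list(loc = loc, frag = s$frag)
  })
}

# parse a bracketed or implicit substituent expression up to `closers`
.parse_subexpr <- function(st, closers, lexicon) {
  cls <- .class_lookup(lexicon)
  items <- list()
  pending_loc <- NULL
  pending_mult <- 1L
  repeat {
    tok <- .pk(st)
    if (is.na(tok)) stop("name parser: unexpected end of name")
    if (tok %in% closers) stop("name parser: empty substituent group")
    if (tok == "-") { .adv(st); next }
    if (.is_digit(tok) || tok == "N") { pending_loc <- .read_locants(st); next }
    if (tok %in% c("(", "[")) {
      closer <- if (tok == "(") ")" else "]"
      .adv(st)
      frag <- .parse_subexpr(st, closer, lexicon)
      .expect(st, closer)
      items <- c(items, .locate(frag, pending_loc, pending_mult))
      pending_loc <- NULL; pending_mult <- 1L
      next
    }
    if (!is.na(cls(tok)) && cls(tok) == "multiplier") {
      pending_mult <- .mult_value[[tok]]; .adv(st); next
    }
    if (!is.na(cls(tok)) && cls(tok) %in% c("prefix", "stereo")) {
      if (cls(tok) == "stereo") stop("name parser: misplaced stereo descriptor")
      grp <- .parse_group_token(st, lexicon)
      nxt <- .pk(st)
      if (is.na(nxt) || nxt %in% closers) {
        # head of this substituent expression
        loc_items <- .int_or_n(items)
        frag <- .build_substituent(grp, loc_items)
        if (!is.null(pending_loc)) {
          stop("name parser: dangling locant before substituent head")
        }
        return(frag)
      }
      # modifier group attached to the upcoming head.  A chain-capable
      # group in modifier position (e.g. "propyl" in
      # "3-methoxypropylcarbamoyl") absorbs the items seen so far: the
      # unbracketed expression is right-nested.
      if (grp %in% c(names(.chain_groups), "acetyl", "anilino", "phenyl") &&
          length(items)) {
        frag <- .build_substituent(grp, .int_or_n(items))
        items <- list(list(loc = NA_character_, frag = frag))
        if (!is.null(pending_loc)) {
          stop("name parser: dangling locant before composite substituent")
        }
      } else {
        frag <- .build_substituent(grp, list())
        items <- c(items, .locate(frag, pending_loc, pending_mult))
      }
      pending_loc <- NULL; pending_mult <- 1L
      next
    }
    stop("name parser: unexpected token \"", tok, "\"")
  }
}

.locate <- function(frag, locs, mult) {
  if (is.null(locs)) {
    if (mult != 1L) stop("name parser: multiplier without matching locants")
    return(list(list(loc = NA_character_, frag = frag)))
  }
  if (mult != 1L && length(locs) != mult) {
    stop("name parser: multiplier does not match the number of locants")
  }
  lapply(locs, function(l) list(loc = l, frag = frag))
}

.int_or_n <- function(items) {
  lapply(items, function(s) {
    if (identical(s$loc, "N")) s
    else list(loc = suppressWarnings(as.integer(s$loc)), frag = s$frag)
  })
}

.class_lookup <- function(lexicon) {
  tab <- lexicon$iupac
  function(tok) {
    m <- tab$class[tab$token == tok]
    if (length(m)) m[1L] else NA_character_
  }
}

.stem_root <- function(stem) {
  for (suffix in c("ane", "an", "")) {
    if (suffix == "" || endsWith(stem, suffix)) {
      root <- if (nzchar(suffix)) substr(stem, 1L, nchar(stem) - nchar(suffix)) else stem
      if (root %in% names(.alkyl_roots)) {
        return(list(n = .alkyl_roots[[root]],
                    form = c(ane = "ane", an = "an")[suffix] %||% "root"))
      }
    }
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Parse an IUPAC name to a structure
#'
#' Rule-based name-to-structure conversion for the nomenclature subset
#' supported by this package (see the package vignette).  The returned
#' SMILES is a valid, not necessarily canonical, encoding of the named
#' structure; pass it through [canonical_smiles()] for identity
#' comparisons.  Unsupported or malformed names raise an error.
#'
#' @param name A single IUPAC name.
#' @param lexicon A [read_lexicon()] lexicon.
#' @return A SMILES string.
#' @export
#' @examples
#' parse_iupac("propan-2-one")
#' canonical_equal(parse_iupac("ethanol"), "CCO")
parse_iupac <- function(name, lexicon = default_lexicon()) {
  .ring_env$counter <- 1L
  tokens <- tokenize_iupac(name, lexicon)$tokens
  st <- .parser_state(tokens)
  cls <- .class_lookup(lexicon)

  stereo <- NULL
  if (identical(.pk(st), "(") && !is.na(.pk(st, 1L)) &&
      identical(cls(.pk(st, 1L)), "stereo")) {
    stereo <- .pk(st, 1L)
    .adv(st); .adv(st); .expect(st, ")")
    .skip_hyphen(st)
    if (!stereo %in% c("E", "Z")) {
      stop("name parser: only E/Z stereo descriptors are supported")
    }
  }

  # prefix substituents, then the parent stem
  items <- list()
  pending_loc <- NULL
  pending_mult <- 1L
  repeat {
    tok <- .pk(st)
    if (is.na(tok)) stop("name parser: no parent stem found")
    if (tok == "-") { .adv(st); next }
    if (.is_digit(tok) || tok == "N") { pending_loc <- .read_locants(st); next }
    if (tok %in% c("(", "[")) {
      closer <- if (tok == "(") ")" else "]"
      .adv(st)
      frag <- .parse_subexpr(st, closer, lexicon)
      .expect(st, closer)
      items <- c(items, .locate(frag, pending_loc, pending_mult))
      pending_loc <- NULL; pending_mult <- 1L
      next
    }
    tc <- cls(tok)
    if (!is.na(tc) && tc == "multiplier") { pending_mult <- .mult_value[[tok]]; .adv(st); next }
    if (!is.na(tc) && tc == "prefix") {
      grp <- .parse_group_token(st, lexicon)
      frag <- .build_substituent(grp, list())
      items <- c(items, .locate(frag, pending_loc, pending_mult))
      pending_loc <- NULL; pending_mult <- 1L
      next
    }
    if (!is.na(tc) && tc == "stem") break
    stop("name parser: unexpected token \"", tok, "\" before parent stem")
  }
  if (!is.null(pending_loc)) stop("name parser: dangling locant before parent")

  stem <- .pk(st); .adv(st)

  if (stem == "benzamide") {
    if (!is.null(stereo)) stop("name parser: stereo descriptor on benzamide")
    nsubs <- Filter(function(s) identical(s$loc, "N"), items)
    rsubs <- .int_locs(Filter(function(s) !identical(s$loc, "N"), items))
    if (!is.na(.pk(st))) stop("name parser: trailing tokens after benzamide")
    namide <- if (length(nsubs)) {
      paste0("N(", paste(vapply(nsubs, function(s) s$frag$smi, ""),
                         collapse = ")("), ")")
    } else "N"
    return(paste0("O=C(", namide, ")", .render_ring(rsubs)))
  }

  info <- .stem_root(stem)
  if (is.null(info)) stop("name parser: unsupported parent stem '", stem, "'")
  n <- info$n
  # a prefix with no locant ("chloromethane", "bromoethane") attaches at C1
  items <- lapply(items, function(s) {
    if (is.na(s$loc)) s$loc <- "1"
    s
  })
  chain_subs <- .int_locs(items)
  ene <- NULL

  suffix_subs <- list()
  add_suffix <- function(kind, locs) {
    for (l in locs) {
      frag <- if (kind == "ol") .frag("O") else .frag("", kind = "oxo")
      suffix_subs[[length(suffix_subs) + 1L]] <<- list(loc = as.integer(l), frag = frag)
    }
  }

  if (info$form == "ane") {
    # alkane, or retained-e suffix group: "-l,l'-<mult><ol|one>"
    if (!is.na(.pk(st))) {
      .expect(st, "-")
      locs <- .read_locants(st)
      .expect(st, "-")
      mult <- 1L
      if (!is.na(.pk(st)) && identical(cls(.pk(st)), "multiplier")) {
        mult <- .mult_value[[.pk(st)]]; .adv(st)
      }
      suff <- .pk(st); .adv(st)
      if (!suff %in% c("ol", "one")) {
        stop("name parser: unsupported suffix '", suff, "' on '", stem, "'")
      }
      if (length(locs) != mult) {
        stop("name parser: suffix multiplier does not match its locants")
      }
      add_suffix(suff, locs)
    }
  } else if (info$form == "an") {
    # elided stem: "-l-ol", "-l-one", or a bare suffix (methanol, ethanol)
    if (identical(.pk(st), "-")) {
      .adv(st)
      locs <- .read_locants(st)
      .expect(st, "-")
      suff <- .pk(st); .adv(st)
      if (!suff %in% c("ol", "one", "al")) {
        stop("name parser: unsupported suffix '", suff, "'")
      }
      if (suff == "al" && !identical(locs, "1")) {
        stop("name parser: -al requires locant 1")
      }
      add_suffix(if (suff == "al") "one" else suff, locs)
    } else if (.pk(st) %in% c("ol", "one", "al")) {
      suff <- .pk(st); .adv(st)
      add_suffix(switch(suff, ol = "ol", one = "one", al = "one"),
                 if (suff == "one") "2" else "1")
    } else {
      stop("name parser: expected a suffix after '", stem, "'")
    }
  } else {
    # bare root: "-p-ene" or "-p-en-q-ol"
    .expect(st, "-")
    p <- as.integer(.read_locants(st))
    .expect(st, "-")
    suff <- .pk(st); .adv(st)
    if (identical(suff, "ene")) {
      ene <- list(pos = p, stereo = stereo); stereo <- NULL
    } else if (identical(suff, "en")) {
      ene <- list(pos = p, stereo = stereo); stereo <- NULL
      .expect(st, "-")
      locs <- .read_locants(st)
      .expect(st, "-")
      .expect(st, "ol")
      add_suffix("ol", locs)
    } else {
      stop("name parser: expected -ene/-en after unsaturation locant")
    }
  }
  if (!is.na(.pk(st))) stop("name parser: trailing tokens after parent")
  if (!is.null(stereo)) stop("name parser: stereo descriptor without a double bond")
  if (length(ene) && (ene$pos < 1L || ene$pos >= n)) {
    stop("name parser: double-bond locant out of range")
  }
  .render_chain(n, c(chain_subs, suffix_subs), ene = ene)
}
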