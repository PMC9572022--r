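#' BEL terms
#'
#' A `bel_term` is one node-level expression of the curation dialect: a
#' namespaced biological entity (protein, gene, RNA, miRNA, chemical
#' abundance, biological process, pathology) or a composite (complex,
#' reaction) holding other terms as components. Terms are the node currency
#' of the knowledge graph; two syntactically different spellings of the same
#' entity share one *canonical key* (see [term_key()]).
#'
#' @param fn Term function, one of
#'   `"protein"`, `"gene"`, `"rna"`, `"mirna"`, `"abundance"`, `"complex"`,
#'   `"bioProcess"`, `"pathology"`, `"reaction"`.
#' @param namespace Namespace of a leaf term (`"HGNC"`, `"CHEBI"`, `"MESH"`,
#'   `"GO"` or `"TEXT"` for free-text entities). Ignored for composites.
#' @param name Entity name within the namespace. Ignored for composites.
#' @param components List of `bel_term` components; required (non-empty) for
#'   `complex` and `reaction`, forbidden otherwise.
#' @param activity `TRUE` if the term carries a molecular-activity modifier
#'   (`act(...)`); activity is a modifier, not part of node identity.
#' @return An object of class `bel_term`.
#' @examples
#' bel_term("protein", "HGNC", "F8")
#' bel_term("complex", components = list(
#'   bel_term("abundance", "CHEBI", "heme"),
#'   bel_term("protein", "HGNC", "PROC")))
#' @export
bel_term <- function(fn, namespace = NULL, name = NULL,
                     components = NULL, activity = FALSE) {
  fn <- match.arg(fn, BEL_FUNCTIONS)
  composite <- fn %in% c("complex", "reaction")
  if (composite) {
    if (is.null(components) || length(components) == 0L)
      stop("'", fn, "' term requires at least one component", call. = FALSE)
    ok <- vapply(components, inherits, logical(1), what = "bel_term")
    if (!all(ok)) stop("all components must be bel_term objects", call. = FALSE)
    namespace <- NA_character_
    name <- NA_character_
  } else {
    if (!length(components) == 0L && !is.null(components))
      stop("only complex/reaction terms may have components", call. = FALSE)
    if (is.null(namespace) || is.null(name) ||
        !nzchar(namespace) || !nzchar(name))
      stop("leaf term requires non-empty namespace and name", call. = FALSE)
    components <- NULL
  }
  structure(
    list(fn = fn, namespace = namespace, name = name,
         components = components, activity = isTRUE(activity)),
    class = "bel_term")
}


## locale-independent sorting (C ordering) so canonical keys and exported
## files are byte-stable across systems
csort <- function(x) {
  if (length(x) == 0) return(character(0))
  sort(x, method = "radix")
}
corder <- function(...) order(..., method = "radix")

BEL_FUNCTIONS <- c("protein", "gene", "rna", "mirna", "abundance",
                   "complex", "bioProcess", "pathology", "reaction")

## short <-> long function spellings of the dialect
BEL_FN_ABBREV <- c(protein = "p", gene = "g", rna = "r", mirna = "m",
                   abundance = "a", complex = "complex", bioProcess = "bp",
                   pathology = "path", reaction = "rxn")

#' Canonical node key of a BEL term
#'
#' Deterministic identity string: function, namespace and upper-cased name
#' for leaves; function plus the sorted keys of the components for
#' composites. Component order and name case therefore never matter, and the
#' activity modifier is excluded (an activity is an aspect of a node, not a
#' different node).
#'
#' @param term A [bel_term()].
#' @return A single string.
#' @examples
#' term_key(parse_term("complex(p(HGNC:F8), p(HGNC:VWF))")) ==
#'   term_key(parse_term("complex(p(HGNC:VWF), p(HGNC:F8))"))
#' @export
term_key <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  if (term$fn %in% c("complex", "reaction")) {
    keys <- csort(vapply(term$components, term_key, character(1)))
    paste0(term$fn, "(", paste(keys, collapse = "|"), ")")
  } else {
    paste0(term$fn, "(", term$namespace, ":", toupper(term$name), ")")
  }
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", serialize_term(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bel_term <- function(x, ...) serialize_term(x)

## quote a name when it is not a bare word
.bel_quote <- function(name) {
  if (grepl("^[A-Za-z0-9_.-]+$", name)) name
  else paste0('"', gsub('"', '\\\\"', name), '"')
}

#' Serialize a BEL term
#'
#' Inverse of [parse_term()]: `parse_term(serialize_term(t))` reproduces `t`.
#' Composite components are emitted in canonical-key order so serialization
#' is deterministic.
#'
#' @param term A [bel_term()].
#' @return A single string in the dialect's surface syntax.
#' @export
serialize_term <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  inner <- if (term$fn %in% c("complex", "reaction")) {
    comps <- term$components[corder(vapply(term$components, term_key,
                                           character(1)))]
    paste0(BEL_FN_ABBREV[[term$fn]], "(",
           paste(vapply(comps, serialize_term, character(1)),
                 collapse = ", "), ")")
  } else {
    paste0(BEL_FN_ABBREV[[term$fn]], "(", term$namespace, ":",
           .bel_quote(term$name), ")")
  }
  if (term$activity) paste0("act(", inner, ")") else inner
}

## ---- term parser (recursive descent over a token cursor) ------------------

.term_fn_lookup <- local({
  c(structure(names(BEL_FN_ABBREV), names = unname(BEL_FN_ABBREV)),
    structure(BEL_FUNCTIONS, names = BEL_FUNCTIONS),
    proteinAbundance = "protein", geneAbundance = "gene",
    rnaAbundance = "rna", microRNAAbundance = "mirna",
    complexAbundance = "complex",
    biologicalProcess = "bioProcess")
})

#' Parse a single BEL term expression
#'
#' Accepts the short (`p`, `g`, `r`, `m`, `a`, `complex`, `bp`, `path`,
#' `rxn`) and long (`proteinAbundance`, ...) function spellings, quoted or
#' bare names, arbitrarily nested complexes/reactions, and the `act(...)`
#' molecular-activity wrapper.
#'
#' @param text A single string holding one term expression.
#' @return A [bel_term()].
#' @examples
#' parse_term("a(CHEBI:heme)")
#' parse_term('bp(GO:"blood coagulation")')
#' @export
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- list(s = text, pos = 1L)
  res <- .pt_term(st)
  st <- res$state
  st <- .pt_ws(st)
  if (st$pos <= nchar(st$s))
    .pt_fail(st, paste0("trailing input '",
                        substring(st$s, st$pos), "'"))
  res$term
}

.pt_fail <- function(st, msg) {
  stop(sprintf("BEL term parse error at position %d: %s", st$pos, msg),
       call. = FALSE)
}

.pt_ws <- function(st) {
  while (st$pos <= nchar(st$s) &&
         substr(st$s, st$pos, st$pos) %in% c(" ", "\t"))
    st$pos <- st$pos + 1L
  st
}

.pt_expect <- function(st, ch) {
  st <- .pt_ws(st)
  if (st$pos > nchar(st$s) || substr(st$s, st$pos, st$pos) != ch)
    .pt_fail(st, paste0("expected '", ch, "'"))
  st$pos <- st$pos + 1L
  st
}

.pt_word <- function(st) {
  st <- .pt_ws(st)
  m <- regexpr("^[A-Za-z][A-Za-z0-9_]*", substring(st$s, st$pos))
  if (m == -1L) .pt_fail(st, "expected identifier")
  w <- substr(st$s, st$pos, st$pos + attr(m, "match.length") - 1L)
  st$pos <- st$pos + attr(m, "match.length")
  list(word = w, state = st)
}

## name token: quoted string (with \" escapes) or bare word
.pt_name <- function(st) {
  st <- .pt_ws(st)
  if (st$pos <= nchar(st$s) && substr(st$s, st$pos, st$pos) == '"') {
    i <- st$pos + 1L
    out <- character(0)
    n <- nchar(st$s)
    while (i <= n) {
      ch <- substr(st$s, i, i)
      if (ch == "\\" && i < n) {
        out <- c(out, substr(st$s, i + 1L, i + 1L)); i <- i + 2L
      } else if (ch == '"') {
        st$pos <- i + 1L
        nm <- paste(out, collapse = "")
        if (!nzchar(nm)) .pt_fail(st, "empty quoted name")
        return(list(name = nm, state = st))
      } else {
        out <- c(out, ch); i <- i + 1L
      }
    }
    .pt_fail(st, "unterminated quoted name")
  }
  m <- regexpr("^[^\\s(),:]+", substring(st$s, st$pos), perl = TRUE)
  if (m == -1L) .pt_fail(st, "empty name")
  nm <- substr(st$s, st$pos, st$pos + attr(m, "match.length") - 1L)
  st$pos <- st$pos + attr(m, "match.length")
  list(name = nm, state = st)
}

.pt_term <- function(st) {
  w <- .pt_word(st); st <- w$state
  if (w$word == "act") {
    st <- .pt_expect(st, "(")
    inner <- .pt_term(st); st <- inner$state
    st <- .pt_expect(st, ")")
    t <- inner$term
    t$activity <- TRUE
    return(list(term = t, state = st))
  }
  fn <- .term_fn_lookup[w$word]
  if (is.na(fn)) .pt_fail(st, paste0("unknown BEL function '", w$word, "'"))
  st <- .pt_expect(st, "(")
  if (fn %in% c("complex", "reaction")) {
    comps <- list()
    repeat {
      res <- .pt_term(st); st <- res$state
      comps <- c(comps, list(res$term))
      st <- .pt_ws(st)
      if (st$pos <= nchar(st$s) && substr(st$s, st$pos, st$pos) == ",") {
        st$pos <- st$pos + 1L
      } else break
    }
    st <- .pt_expect(st, ")")
    return(list(term = bel_term(fn, components = comps), state = st))
  }
  ns <- .pt_word(st); st <- ns$state
  st <- .pt_expect(st, ":")
  nm <- .pt_name(st); st <- nm$state
  st <- .pt_expect(st, ")")
  list(term = bel_term(fn, ns$word, nm$name), state = st)
}

## ---- entity normalization --------------------------------------------------

#' Default heme synonym and formulation tables
#'
#' The curation rule for the heme entity: the free pool of
#' iron-protoporphyrin IX appears in the literature as "heme", "hemin"
#' (the Fe(III) chloride salt) and "hematin" (the Fe(III) hydroxide form);
#' all are curated as a single `a(CHEBI:heme)` entity. Pharmaceutical
#' formulations developed to *avoid* labile-heme side effects (heme
#' arginate, heme-albumin) are excluded from the graph entirely. Both tables
#' ship as editable TSVs under `inst/extdata/` and these helpers read them.
#'
#' @return `heme_synonyms()`: character vector of case-insensitive names
#'   that canonicalize to heme. `heme_blocklist()`: character vector of
#'   excluded formulation names.
#' @export
heme_synonyms <- function() {
  path <- system.file("extdata", "heme_synonyms.tsv", package = "coagkg")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tolower(tab$name[tab$action == "canonicalize"])
}

#' @rdname heme_synonyms
#' @export
heme_blocklist <- function() {
  path <- system.file("extdata", "heme_synonyms.tsv", package = "coagkg")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tolower(tab$name[tab$action == "exclude"])
}

#' Marker for curation-excluded entities
#'
#' Sentinel returned by [normalize_entity()] for terms on the formulation
#' blocklist; statements touching an excluded entity are dropped before
#' graph compilation.
#' @return The exclusion sentinel (class `bel_excluded`).
#' @export
bel_excluded <- function() structure(list(), class = "bel_excluded")

#' @export
print.bel_excluded <- function(x, ...) {
  cat("<EXCLUDED entity>\n"); invisible(x)
}

#' @param x Object to test.
#' @rdname bel_excluded
#' @export
is_excluded <- function(x) inherits(x, "bel_excluded")

#' Normalize an entity term
#'
#' Applies the heme curation rules to a leaf term: synonyms of labile heme
#' (case-insensitive, any namespace) collapse to the canonical
#' `a(CHEBI:heme)` node; formulation names return the [bel_excluded()]
#' sentinel; every other term passes through unchanged. Idempotent.
#'
#' @param term A leaf [bel_term()].
#' @param synonyms,blocklist Case-insensitive name vectors; defaults read
#'   the bundled tables.
#' @return A `bel_term` or the `bel_excluded` sentinel.
#' @examples
#' normalize_entity(parse_term("a(TEXT:hemin)"))       # -> a(CHEBI:heme)
#' is_excluded(normalize_entity(parse_term('a(TEXT:"heme arginate")')))
#' @export
normalize_entity <- function(term, synonyms = heme_synonyms(),
                             blocklist = heme_blocklist()) {
  stopifnot(inherits(term, "bel_term"))
  if (term$fn %in% c("complex", "reaction"))
    stop("normalize_entity() operates on leaf terms; use normalize_term()",
         call. = FALSE)
  nm <- tolower(term$name)
  if (nm %in% blocklist) return(bel_excluded())
  if (nm %in% synonyms) {
    out <- bel_term("abundance", "CHEBI", "heme", activity = term$activity)
    return(out)
  }
  term
}

#' Normalize a term tree
#'
#' Recursive companion of [normalize_entity()]: composites are normalized
#' component-wise, and a composite containing an excluded component is
#' itself excluded (a heme-arginate complex carries no curatable content).
#'
#' @inheritParams normalize_entity
#' @return A `bel_term` or the `bel_excluded` sentinel.
#' @export
normalize_term <- function(term, synonyms = heme_synonyms(),
                           blocklist = heme_blocklist()) {
  stopifnot(inherits(term, "bel_term"))
  if (term$fn %in% c("complex", "reaction")) {
    comps <- lapply(term$components, normalize_term,
                    synonyms = synonyms, blocklist = blocklist)
    if (any(vapply(comps, is_excluded, logical(1)))) return(bel_excluded())
    out <- bel_term(term$fn, components = comps, activity = term$activity)
    return(out)
  }
  normalize_entity(term, synonyms = synonyms, blocklist = blocklist)
}
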