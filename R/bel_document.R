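#' Experimental-context annotation set
#'
#' The curation dialect attaches experimental context to each statement:
#' the cell type and species the observation was made in, the experimental
#' setting (`in_vitro`, `in_vivo`, `ex_vivo`), the heme dose applied (value,
#' unit and an `up_to` qualifier for ceiling doses), the administration
#' route, and the equilibrium dissociation constant K_D when the statement
#' reports direct heme binding. Unknown annotation keys found in a document
#' are preserved verbatim in `extras`.
#'
#' @param cell_type,species Optional free-text strings.
#' @param setting One of `"in_vitro"`, `"in_vivo"`, `"ex_vivo"` or `NA`.
#' @param dose_value,dose_unit,dose_qualifier Dose; unit one of
#'   `"µM"`, `"mM"`, `"nmol"`, `"µmol/kg"`, `"mg/kg"`; qualifier
#'   `"exact"` or `"up_to"`.
#' @param route One of `"incubation"`, `"intravenous"`, `"retroorbital"`,
#'   `"other"` or `NA`.
#' @param kd_value,kd_unit Binding affinity; unit `"nM"` or `"µM"`;
#'   value must be positive.
#' @param dose_text Verbatim dose string kept when the dose did not parse.
#' @param extras Named list of verbatim unknown-key annotations.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(cell_type = NA_character_,
                           species = NA_character_,
                           setting = NA_character_,
                           dose_value = NA_real_, dose_unit = NA_character_,
                           dose_qualifier = NA_character_,
                           route = NA_character_,
                           kd_value = NA_real_, kd_unit = NA_character_,
                           dose_text = NA_character_,
                           extras = list()) {
  if (!is.na(setting))
    setting <- match.arg(setting, c("in_vitro", "in_vivo", "ex_vivo"))
  if (!is.na(route))
    route <- match.arg(route, c("incubation", "intravenous", "retroorbital",
                                "other"))
  if (!is.na(dose_qualifier))
    dose_qualifier <- match.arg(dose_qualifier, c("exact", "up_to"))
  if (!is.na(dose_value) && is.na(dose_unit))
    stop("dose_value requires dose_unit", call. = FALSE)
  if (!is.na(dose_unit))
    dose_unit <- match.arg(dose_unit, DOSE_UNITS)
  if (!is.na(kd_value)) {
    if (is.na(kd_unit)) stop("kd_value requires kd_unit", call. = FALSE)
    if (kd_value <= 0) stop("kd_value must be positive", call. = FALSE)
  }
  if (!is.na(kd_unit)) kd_unit <- match.arg(kd_unit, KD_UNITS)
  structure(list(cell_type = cell_type, species = species, setting = setting,
                 dose_value = dose_value, dose_unit = dose_unit,
                 dose_qualifier = dose_qualifier, route = route,
                 kd_value = kd_value, kd_unit = kd_unit,
                 dose_text = dose_text, extras = extras),
            class = "annotation_set")
}

DOSE_UNITS <- c("\u00b5M", "mM", "nmol", "\u00b5mol/kg", "mg/kg")
KD_UNITS <- c("nM", "\u00b5M")
BEL_RELATIONS <- c("increases", "directlyIncreases", "decreases",
                   "directlyDecreases", "association", "regulates")
.rel_symbols <- c("->" = "increases", "=>" = "directlyIncreases",
                  "-|" = "decreases", "=|" = "directlyDecreases",
                  "--" = "association", "reg" = "regulates")

#' A curated BEL statement
#'
#' One subject--relation--object assertion with its provenance (PMID
#' citation, evidence sentence) and experimental-context annotations.
#'
#' @param subject,object [bel_term()] subject and object.
#' @param relation One of `increases`, `directlyIncreases`, `decreases`,
#'   `directlyDecreases`, `association`, `regulates`.
#' @param citation PMID digits as a string, or `"NA"`.
#' @param evidence Free-text supporting sentence.
#' @param annotations An [annotation_set()].
#' @return An object of class `bel_statement`.
#' @export
bel_statement <- function(subject, relation, object, citation = "NA",
                          evidence = "", annotations = annotation_set()) {
  stopifnot(inherits(subject, "bel_term"), inherits(object, "bel_term"),
            inherits(annotations, "annotation_set"))
  relation <- match.arg(relation, BEL_RELATIONS)
  if (!grepl("^(\\d+|NA)$", citation))
    stop("citation must be PMID digits or 'NA'", call. = FALSE)
  structure(list(subject = subject, relation = relation, object = object,
                 citation = citation, evidence = evidence,
                 annotations = annotations),
            class = "bel_statement")
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", serialize_term(x$subject), " ",
      names(.rel_symbols)[match(x$relation, .rel_symbols)], " ",
      serialize_term(x$object), "  [PMID:", x$citation, "]\n", sep = "")
  invisible(x)
}

#' @export
print.bel_document <- function(x, ...) {
  cat("<bel_document> '", x$header$name, "' v", x$header$version, ": ",
      length(x$statements), " statements\n", sep = "")
  invisible(x)
}

## ---- dose / KD micro-parsers ----------------------------------------------

.num_re <- "[0-9]+(?:\\.[0-9]+)?"

parse_dose <- function(text) {
  text <- trimws(text)
  t2 <- gsub("uM", "\u00b5M", gsub("umol", "\u00b5mol", text, fixed = TRUE),
             fixed = TRUE)
  unit_re <- paste(gsub("/", "\\\\/", DOSE_UNITS), collapse = "|")
  pat <- paste0("^(up to\\s+)?(", .num_re, ")\\s*(", unit_re, ")$")
  m <- regmatches(t2, regexec(pat, t2, perl = TRUE))[[1]]
  if (length(m) == 0)
    return(list(ok = FALSE, text = text))
  list(ok = TRUE,
       qualifier = if (nzchar(m[2])) "up_to" else "exact",
       value = as.numeric(m[3]), unit = m[4])
}

parse_kd <- function(text) {
  t2 <- gsub("uM", "\u00b5M", trimws(text), fixed = TRUE)
  pat <- paste0("^~?(", .num_re, ")\\s*(nM|\u00b5M)$")
  m <- regmatches(t2, regexec(pat, t2, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  list(value = as.numeric(m[2]), unit = m[3])
}

## ---- document parser -------------------------------------------------------

## keys bound to annotation_set fields; Note is recognized (no warning)
## but kept verbatim in extras, like any unknown key
ANNOTATION_FIELD_KEYS <- c("Citation", "Evidence", "CellType", "Species",
                           "Setting", "Dose", "Route", "KD")
KNOWN_ANNOTATIONS <- c(ANNOTATION_FIELD_KEYS, "Note")

.setting_lookup <- c("in vitro" = "in_vitro", "in_vivo" = "in_vivo",
                     "in vivo" = "in_vivo", "ex vivo" = "ex_vivo",
                     "in_vitro" = "in_vitro", "ex_vivo" = "ex_vivo")

.state_to_annotations <- function(state) {
  ann <- annotation_set()
  if (!is.null(state$CellType)) ann$cell_type <- state$CellType
  if (!is.null(state$Species)) ann$species <- state$Species
  if (!is.null(state$Setting)) {
    s <- .setting_lookup[tolower(state$Setting)]
    ann$setting <- if (is.na(s)) NA_character_ else unname(s)
  }
  if (!is.null(state$Route)) {
    r <- tolower(state$Route)
    ann$route <- if (r %in% c("incubation", "intravenous", "retroorbital"))
      r else "other"
  }
  if (!is.null(state$Dose)) {
    d <- parse_dose(state$Dose)
    if (d$ok) {
      ann$dose_value <- d$value; ann$dose_unit <- d$unit
      ann$dose_qualifier <- d$qualifier
    } else {
      ann$dose_text <- d$text
    }
  }
  if (!is.null(state$KD)) {
    k <- parse_kd(state$KD)
    if (!is.null(k)) { ann$kd_value <- k$value; ann$kd_unit <- k$unit }
  }
  extra_keys <- setdiff(names(state), ANNOTATION_FIELD_KEYS)
  if (length(extra_keys))
    ann$extras <- state[csort(extra_keys)]
  ann
}

.unquote <- function(x) {
  x <- trimws(x)
  if (grepl('^".*"$', x)) gsub('\\\\"', '"', substr(x, 2L, nchar(x) - 1L))
  else x
}

#' Parse a BEL script document
#'
#' Reads the curation dialect: one statement per line, `SET Key = "value"` /
#' `UNSET Key` / `UNSET ALL` annotation state, `SET DOCUMENT ...` header
#' metadata, `DEFINE NAMESPACE ...` declarations, `#` comments. Active
#' annotations (including the PMID citation and evidence sentence) are bound
#' to each following statement. Every input line is accounted for: it
#' becomes a statement, a recorded error, or a blank/comment/directive line.
#'
#' @param text Either a single string or a character vector of lines.
#' @param strict If `TRUE` (default) the first malformed line aborts with an
#'   error naming the line; if `FALSE` malformed lines are collected in the
#'   `errors` field and parsing continues (the lenient mode exists because
#'   externally curated documents may differ cosmetically from this
#'   dialect).
#' @return A `bel_document`: list with `statements`, `header` (`name`,
#'   `version`, `namespaces`), `errors` (data frame of line/ message), and
#'   `line_counts` (statements, errors, other — sums to the input length).
#' @examples
#' doc <- parse_document(c(
#'   'SET Citation = "12345"',
#'   'SET Setting = "in vitro"',
#'   'p(HGNC:F8) -| bp(GO:"blood coagulation")'))
#' doc$statements[[1]]$annotations$setting
#' @export
parse_document <- function(text, strict = TRUE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- text
  state <- list()
  header <- list(name = "", version = "", namespaces = character(0))
  statements <- list()
  errs <- list()
  n_other <- 0L
  fail <- function(i, msg) {
    if (strict)
      stop(sprintf("BEL parse error at line %d: %s", i, msg), call. = FALSE)
    errs[[length(errs) + 1L]] <<- data.frame(line = i, message = msg,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) { n_other <- n_other + 1L; next }
    if (grepl("^SET\\s+DOCUMENT\\s", ln)) {
      m <- regmatches(ln, regexec(
        "^SET\\s+DOCUMENT\\s+(\\w+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m)) {
        key <- tolower(m[2])
        if (key %in% c("name", "version")) header[[key]] <- .unquote(m[3])
      }
      n_other <- n_other + 1L; next
    }
    if (grepl("^DEFINE\\s+NAMESPACE\\s", ln)) {
      m <- regmatches(ln, regexec("^DEFINE\\s+NAMESPACE\\s+(\\w+)", ln))[[1]]
      if (length(m)) header$namespaces <- union(header$namespaces, m[2])
      n_other <- n_other + 1L; next
    }
    if (grepl("^UNSET\\s", ln)) {
      key <- trimws(sub("^UNSET\\s+", "", ln))
      state <- if (identical(key, "ALL")) list() else
        state[setdiff(names(state), key)]
      n_other <- n_other + 1L; next
    }
    if (grepl("^SET\\s", ln)) {
      m <- regmatches(ln, regexec("^SET\\s+(\\w+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) == 0) { fail(i, "malformed SET directive"); next }
      key <- m[2]
      val <- m[3]
      if (grepl("^\\{", val)) {
        ## list-style citation {"PubMed", "...", "12345"}: last element
        parts <- regmatches(val, gregexpr('"((?:[^"\\\\]|\\\\.)*)"', val))[[1]]
        val <- if (length(parts)) .unquote(parts[length(parts)]) else val
      } else val <- .unquote(val)
      if (!key %in% KNOWN_ANNOTATIONS)
        warning(sprintf("line %d: unknown annotation key '%s' preserved",
                        i, key), call. = FALSE)
      state[[key]] <- val
      n_other <- n_other + 1L; next
    }
    ## statement line: subject term, relation token, object term
    stmt <- tryCatch(.parse_statement_line(ln, state),
                     error = function(e) conditionMessage(e))
    if (is.character(stmt)) { fail(i, stmt); next }
    statements[[length(statements) + 1L]] <- stmt
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(0), message = character(0))
  structure(list(statements = statements, header = header, errors = errors,
                 line_counts = c(statements = length(statements),
                                 errors = nrow(errors), other = n_other)),
            class = "bel_document")
}

.parse_statement_line <- function(ln, state) {
  st <- list(s = ln, pos = 1L)
  subj <- .pt_term(st); st <- .pt_ws(subj$state)
  m <- regexpr("^(=>|->|-\\||=\\||--|[A-Za-z]+)", substring(st$s, st$pos))
  if (m == -1L) stop("expected relation after subject term", call. = FALSE)
  tok <- substr(st$s, st$pos, st$pos + attr(m, "match.length") - 1L)
  st$pos <- st$pos + attr(m, "match.length")
  relation <- if (tok %in% names(.rel_symbols)) unname(.rel_symbols[tok])
  else if (tok %in% BEL_RELATIONS) tok
  else stop(sprintf("unknown relation '%s'", tok), call. = FALSE)
  obj <- .pt_term(st); st <- .pt_ws(obj$state)
  if (st$pos <= nchar(st$s))
    stop(sprintf("trailing content '%s' after object term",
                 substring(st$s, st$pos)), call. = FALSE)
  citation <- if (!is.null(state$Citation) &&
                  grepl("^(\\d+|NA)$", state$Citation)) state$Citation
  else "NA"
  evidence <- if (!is.null(state$Evidence)) state$Evidence else ""
  bel_statement(subj$term, relation, obj$term, citation = citation,
                evidence = evidence,
                annotations = .state_to_annotations(state))
}

#' Read a BEL script from disk
#' @param path Path to a UTF-8 `.bel` file.
#' @inheritParams parse_document
#' @return A `bel_document`; see [parse_document()].
#' @export
read_bel <- function(path, strict = TRUE) {
  doc <- parse_document(readLines(path, encoding = "UTF-8", warn = FALSE),
                        strict = strict)
  if (!nzchar(doc$header$name))
    doc$header$name <- basename(path)
  doc
}

## ---- serializer ------------------------------------------------------------

.ann_to_state <- function(stmt) {
  a <- stmt$annotations
  state <- list(Citation = stmt$citation, Evidence = stmt$evidence)
  if (!is.na(a$cell_type)) state$CellType <- a$cell_type
  if (!is.na(a$species)) state$Species <- a$species
  if (!is.na(a$setting)) state$Setting <- chartr("_", " ", a$setting)
  if (!is.na(a$dose_value)) {
    pre <- if (identical(a$dose_qualifier, "up_to")) "up to " else ""
    state$Dose <- paste0(pre, format(a$dose_value, scientific = FALSE),
                         " ", a$dose_unit)
  } else if (!is.na(a$dose_text)) state$Dose <- a$dose_text
  if (!is.na(a$route)) state$Route <- a$route
  if (!is.na(a$kd_value))
    state$KD <- paste0(format(a$kd_value, scientific = FALSE), " ", a$kd_unit)
  for (k in names(a$extras)) state[[k]] <- a$extras[[k]]
  state
}

#' Serialize a document back to BEL script text
#'
#' Emits header metadata, then the statements with *minimized* annotation
#' blocks: a `SET` line appears only when the annotation state changes
#' relative to the previous statement, and `UNSET` when a key becomes
#' inactive. Output is deterministic (fixed key order) and re-parses to an
#' equal document.
#'
#' @param doc A `bel_document`.
#' @return Character vector of lines.
#' @export
serialize_document <- function(doc) {
  stopifnot(inherits(doc, "bel_document"))
  out <- c(sprintf('SET DOCUMENT Name = "%s"', doc$header$name),
           sprintf('SET DOCUMENT Version = "%s"', doc$header$version))
  for (ns in doc$header$namespaces)
    out <- c(out, sprintf("DEFINE NAMESPACE %s", ns))
  out <- c(out, "")
  active <- list()
  for (stmt in doc$statements) {
    want <- .ann_to_state(stmt)
    gone <- setdiff(names(active), names(want))
    for (k in csort(gone)) out <- c(out, paste("UNSET", k))
    keys <- c(intersect(KNOWN_ANNOTATIONS, names(want)),
              csort(setdiff(names(want), KNOWN_ANNOTATIONS)))
    for (k in keys) {
      if (!identical(active[[k]], want[[k]]))
        out <- c(out, sprintf('SET %s = "%s"', k,
                              gsub('"', '\\\\"', want[[k]])))
    }
    active <- want
    out <- c(out, paste(serialize_term(stmt$subject),
                        names(.rel_symbols)[match(stmt$relation,
                                                  .rel_symbols)],
                        serialize_term(stmt$object)))
  }
  out
}

#' Write a document as a `.bel` file
#' @param doc A `bel_document`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bel <- function(doc, path) {
  writeLines(serialize_document(doc), path, useBytes = FALSE)
  invisible(path)
}
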