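#' Read GO cellular-component annotations from a GAF 2.2 file
#'
#' Only cellular-component rows (aspect `C`) are used; rows whose qualifier
#' contains `NOT` are excluded; gene symbols are upper-cased; evidence codes
#' are retained so downstream steps can filter (e.g. drop electronically
#' inferred `IEA` annotations).
#'
#' @param path GAF 2.2 file (tab-separated, 17 columns, `!` comments).
#' @param keep_evidence Optional character vector of evidence codes to
#'   keep; default keeps all.
#' @return Data frame with columns `symbol`, `go_id`, `evidence`.
#' @export
read_gaf <- function(path, keep_evidence = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0)
    return(data.frame(symbol = character(0), go_id = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L))
    stop(sprintf("malformed GAF row at line %d (%d fields, need >= 15)",
                 lineno[which(nf < 15L)[1]], nf[nf < 15L][1]), call. = FALSE)
  m <- t(vapply(fields, function(f) f[c(3, 4, 5, 7, 9)], character(5)))
  bad_go <- !grepl("^GO:\\d{7}$", m[, 3])
  if (any(bad_go))
    stop(sprintf("malformed GO id '%s' at line %d", m[bad_go, 3][1],
                 lineno[bad_go][1]), call. = FALSE)
  ok <- m[, 5] == "C" & !grepl("NOT", m[, 2], fixed = TRUE)
  out <- data.frame(symbol = toupper(m[ok, 1]), go_id = m[ok, 3],
                    evidence = m[ok, 4], stringsAsFactors = FALSE)
  if (!is.null(keep_evidence))
    out <- out[out$evidence %in% keep_evidence, , drop = FALSE]
  rownames(out) <- NULL
  unique(out)
}

#' Compartment mapping table
#'
#' Maps GO cellular-component terms to the three coarse compartments the
#' crosstalk analysis is stratified by. The default ships as an editable
#' TSV: extracellular (extracellular region GO:0005576, extracellular space
#' GO:0005615), membrane (membrane GO:0016020, plasma membrane GO:0005886,
#' external side of plasma membrane GO:0009897), intracellular
#' (intracellular GO:0005622, cytoplasm GO:0005737, cytosol GO:0005829,
#' nucleus GO:0005634).
#'
#' @param path Optional TSV with columns `go_id`, `compartment`; default
#'   reads the bundled table.
#' @return Data frame of class `compartment_mapping`.
#' @export
compartment_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cc_compartments.tsv", package = "coagkg")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("go_id", "compartment") %in% names(tab)))
  if (any(!grepl("^GO:\\d{7}$", tab$go_id)))
    stop("syntactically invalid GO ids in mapping", call. = FALSE)
  if (any(!tab$compartment %in% COMPARTMENTS))
    stop("compartments must be one of: ",
         paste(COMPARTMENTS, collapse = ", "), call. = FALSE)
  class(tab) <- c("compartment_mapping", "data.frame")
  tab
}

COMPARTMENTS <- c("extracellular", "membrane", "intracellular")

#' Classify a protein's compartments
#'
#' Union of the mapped compartments over the protein's CC terms;
#' multi-label is allowed (a receptor with both plasma-membrane and cytosol
#' annotations is counted in both compartments — the convention that lets
#' per-compartment totals exceed the protein total). A symbol with no
#' mappable CC term is unassigned (empty set).
#'
#' @param go_ids Character vector of GO CC ids annotated to one symbol.
#' @param mapping A [compartment_mapping()].
#' @param ancestors Optional named list (`go_id` -> character vector of
#'   ancestor ids, from [read_obo_ancestors()]); when given, each annotated
#'   term also contributes its is_a/part_of ancestors before mapping.
#' @return Character vector, subset of
#'   `c("extracellular", "membrane", "intracellular")`.
#' @export
classify_compartments <- function(go_ids, mapping = compartment_mapping(),
                                  ancestors = NULL) {
  if (!is.null(ancestors)) {
    extra <- unlist(ancestors[intersect(go_ids, names(ancestors))])
    go_ids <- union(go_ids, extra)
  }
  csort(unique(mapping$compartment[mapping$go_id %in% go_ids]))
}

#' Build a localization table
#'
#' Applies [classify_compartments()] to every requested symbol. A symbol
#' appears either in the labelled map or, when it has no mappable CC term
#' (or no annotation at all), in `unassigned` — never in both.
#'
#' @param symbols Character vector of HGNC symbols to classify.
#' @param annotations GAF table from [read_gaf()].
#' @param mapping A [compartment_mapping()].
#' @param ancestors Optional ancestor closure, see
#'   [classify_compartments()].
#' @return A `localization_table`: list with `labels` (named list symbol ->
#'   compartment set) and `unassigned` (character vector).
#' @export
build_localization <- function(symbols, annotations,
                               mapping = compartment_mapping(),
                               ancestors = NULL) {
  symbols <- unique(toupper(symbols))
  by_sym <- split(annotations$go_id, annotations$symbol)
  labels <- list(); unassigned <- character(0)
  for (s in csort(symbols)) {
    comp <- classify_compartments(by_sym[[s]], mapping, ancestors)
    if (length(comp) == 0) unassigned <- c(unassigned, s)
    else labels[[s]] <- comp
  }
  structure(list(labels = labels, unassigned = unassigned),
            class = "localization_table")
}

#' @export
print.localization_table <- function(x, ...) {
  part <- partition_compartments(names(x$labels), x)
  cat("<localization_table> ", length(x$labels), " classified (",
      paste(sprintf("%s: %d", names(part), lengths(part)), collapse = ", "),
      "), ", length(x$unassigned), " unassigned\n", sep = "")
  invisible(x)
}

#' Partition symbols by compartment
#'
#' Each compartment's set contains the symbols whose label set includes
#' that compartment; a multi-label protein appears in several sets, so the
#' per-compartment sizes can sum to more than the number of classified
#' proteins.
#'
#' @param symbols Symbols to partition (silently restricted to classified
#'   ones).
#' @param table A `localization_table` from [build_localization()].
#' @return Named list of three sorted character vectors
#'   (`extracellular`, `membrane`, `intracellular`).
#' @export
partition_compartments <- function(symbols, table) {
  stopifnot(inherits(table, "localization_table"))
  symbols <- intersect(unique(toupper(symbols)), names(table$labels))
  out <- lapply(COMPARTMENTS, function(cmp)
    csort(symbols[vapply(table$labels[symbols],
                        function(l) cmp %in% l, logical(1))]))
  names(out) <- COMPARTMENTS
  out
}

#' Minimal OBO ancestor closure
#'
#' Reads `[Term]` stanzas of an OBO file and returns, for every term, the
#' transitive closure over `is_a` and `part_of` relationships. This powers
#' the optional ancestor-propagation mode of [classify_compartments()]
#' (off by default: the flat mapping is reproducible across ontology
#' releases).
#'
#' @param path OBO file path.
#' @return Named list: term id -> character vector of ancestor ids
#'   (excluding the term itself).
#' @export
read_obo_ancestors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      if (is.null(parents[[cur]])) parents[[cur]] <- character(0)
    } else if (!is.null(cur) && startsWith(ln, "is_a:")) {
      p <- trimws(strsplit(sub("^is_a:", "", ln), "!", fixed = TRUE)[[1]][1])
      parents[[cur]] <- union(parents[[cur]], p)
    } else if (!is.null(cur) &&
               grepl("^relationship:\\s*part_of\\s", ln)) {
      p <- trimws(strsplit(sub("^relationship:\\s*part_of", "", ln),
                           "!", fixed = TRUE)[[1]][1])
      parents[[cur]] <- union(parents[[cur]], p)
    }
  }
  ## transitive closure (graphs are tiny DAGs; fixed-point iteration)
  anc <- parents
  repeat {
    changed <- FALSE
    for (id in names(anc)) {
      more <- unique(unlist(anc[intersect(anc[[id]], names(anc))]))
      new <- union(anc[[id]], more)
      if (length(new) > length(anc[[id]])) { anc[[id]] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  anc
}
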