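#' Harmonized pathway network
#'
#' A database pathway (KEGG / Reactome / WikiPathways), consumed as a
#' harmonized flat export rather than from the native KGML/GPML/BioPAX
#' schema: either a TSV edge list (`source, source_class, interaction,
#' target, target_class`) or a GMT membership line (nodes only, no edges).
#' Protein nodes are keyed by upper-case HGNC symbol; metabolites and
#' processes keep their (case-folded for matching) names, because clot
#' constituents such as fibrin and small molecules such as thromboxane A2
#' legitimately participate in network overlap.
#'
#' @param pathway_ids Data frame with columns `source_db` (`"KEGG"`,
#'   `"Reactome"`, `"WikiPathways"`) and `accession`.
#' @param nodes Data frame with columns `symbol`, `entity_class`
#'   (`"protein"`, `"metabolite"`, `"process"`), `xrefs`, `pathways`
#'   (semicolon-joined accessions the node belongs to).
#' @param edges Data frame with columns `source`, `interaction`, `target`.
#' @return An object of class `pathway_network`.
#' @export
pathway_network <- function(pathway_ids = .empty_pathway_ids(),
                            nodes = .empty_pw_nodes(),
                            edges = .empty_pw_edges()) {
  stopifnot(all(c("source_db", "accession") %in% names(pathway_ids)),
            all(c("symbol", "entity_class") %in% names(nodes)),
            all(c("source", "interaction", "target") %in% names(edges)))
  bad <- !pathway_ids$source_db %in% c("KEGG", "Reactome", "WikiPathways")
  if (any(bad))
    stop("unknown source_db: ", paste(pathway_ids$source_db[bad],
                                      collapse = ", "), call. = FALSE)
  if (any(!nzchar(pathway_ids$accession)))
    stop("empty pathway accession", call. = FALSE)
  if (is.null(nodes$xrefs)) nodes$xrefs <- ""
  if (is.null(nodes$pathways)) nodes$pathways <- ""
  ## protein symbols are upper-cased HGNC; named entities case-folded;
  ## `unmapped:`-prefixed placeholders keep their marker verbatim
  prot_up <- nodes$entity_class == "protein" &
    !startsWith(nodes$symbol, "unmapped:")
  nodes$symbol[prot_up] <- toupper(nodes$symbol[prot_up])
  non_prot <- nodes$entity_class != "protein"
  nodes$symbol[non_prot] <- tolower(nodes$symbol[non_prot])
  edges$source <- .pw_fold(edges$source, nodes)
  edges$target <- .pw_fold(edges$target, nodes)
  dangling <- setdiff(c(edges$source, edges$target), nodes$symbol)
  if (length(dangling))
    stop("edge endpoints missing from node table: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  nodes <- nodes[corder(nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[corder(edges$source, edges$interaction, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(pathway_ids = pathway_ids, nodes = nodes, edges = edges),
            class = "pathway_network")
}

## fold an endpoint vector to the node table's casing
.pw_fold <- function(x, nodes) {
  up <- toupper(x); lo <- tolower(x)
  out <- ifelse(up %in% nodes$symbol[nodes$entity_class == "protein"],
                up, ifelse(lo %in% nodes$symbol, lo, x))
  out
}

.empty_pathway_ids <- function()
  data.frame(source_db = character(0), accession = character(0),
             stringsAsFactors = FALSE)
.empty_pw_nodes <- function()
  data.frame(symbol = character(0), entity_class = character(0),
             xrefs = character(0), pathways = character(0),
             stringsAsFactors = FALSE)
.empty_pw_edges <- function()
  data.frame(source = character(0), interaction = character(0),
             target = character(0), stringsAsFactors = FALSE)

#' @export
print.pathway_network <- function(x, ...) {
  ids <- paste(x$pathway_ids$source_db, x$pathway_ids$accession, sep = ":")
  cat("<pathway_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges", if (length(ids)) paste0(" [", paste(ids, collapse = ", "),
                                        "]"), "\n", sep = "")
  invisible(x)
}

#' Load a pathway export
#'
#' Two harmonized formats are read. `tsv_edgelist`: header
#' `source<TAB>source_class<TAB>interaction<TAB>target<TAB>target_class`,
#' one interaction per row (lines starting `#` are comments; a `#pathway`
#' comment of the form `#pathway<TAB>Reactome<TAB>R-HSA-140837` declares
#' the accession). `gmt`: standard gene-set dialect,
#' `accession<TAB>description<TAB>member1<TAB>member2...`; GMT yields
#' membership only, the edge set is empty.
#'
#' @param path File path.
#' @param format `"tsv_edgelist"` or `"gmt"`; default guessed from the
#'   file extension.
#' @param source_db,accession Pathway identity used when the file declares
#'   none (TSV) or for all lines (GMT source database).
#' @return A [pathway_network()].
#' @export
load_pathway <- function(path, format = c("auto", "tsv_edgelist", "gmt"),
                         source_db = "Reactome", accession = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt"
  else "tsv_edgelist"
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    warning("empty pathway file: ", path, call. = FALSE)
    return(pathway_network())
  }
  if (format == "gmt") .load_gmt(lines, source_db)
  else .load_tsv_edgelist(lines, source_db, accession, path)
}

.load_tsv_edgelist <- function(lines, source_db, accession, path) {
  db <- source_db; acc <- accession
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      f <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
      if (length(f) >= 3 && identical(tolower(f[1]), "pathway")) {
        db <- f[2]; acc <- f[3]
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (identical(tolower(f[1]), "source")) next  # header row
    if (length(f) != 5L)
      stop(sprintf("malformed edge-list row at line %d of %s (%d fields)",
                   i, path, length(f)), call. = FALSE)
    rows[[length(rows) + 1L]] <- f
  }
  if (is.null(acc)) acc <- tools::file_path_sans_ext(basename(path))
  m <- do.call(rbind, rows)
  classes <- c("protein", "metabolite", "process")
  bad <- !c(m[, 2], m[, 5]) %in% classes
  if (any(bad))
    stop("unknown entity class: ",
         paste(unique(c(m[, 2], m[, 5])[bad]), collapse = ", "),
         call. = FALSE)
  nodes <- unique(data.frame(symbol = c(m[, 1], m[, 4]),
                             entity_class = c(m[, 2], m[, 5]),
                             stringsAsFactors = FALSE))
  nodes$xrefs <- ""
  nodes$pathways <- acc
  edges <- data.frame(source = m[, 1], interaction = m[, 3],
                      target = m[, 4], stringsAsFactors = FALSE)
  pathway_network(
    data.frame(source_db = db, accession = acc, stringsAsFactors = FALSE),
    nodes, edges)
}

.load_gmt <- function(lines, source_db) {
  ids <- list(); nodes <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT row at line %d (need accession, ",
                   i), "description and at least one member", call. = FALSE)
    acc <- f[1]
    ids[[length(ids) + 1L]] <- acc
    for (s in f[-(1:2)]) {
      if (!nzchar(s)) next
      cls <- if (grepl("^[a-z]", s)) "nonprotein" else "protein"
      key <- if (cls == "protein") toupper(s) else tolower(s)
      prev <- nodes[[key]]
      nodes[[key]] <- list(
        class = if (cls == "protein") "protein" else "metabolite",
        pathways = union(prev$pathways, acc))
    }
  }
  nn <- names(nodes)
  ndf <- data.frame(
    symbol = nn,
    entity_class = vapply(nodes, `[[`, character(1), "class",
                          USE.NAMES = FALSE),
    xrefs = "",
    pathways = vapply(nodes, function(n)
      paste(csort(n$pathways), collapse = ";"), character(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  pathway_network(
    data.frame(source_db = source_db, accession = unlist(ids),
               stringsAsFactors = FALSE),
    ndf, .empty_pw_edges())
}

#' Symbol-mapping table
#'
#' Maps foreign identifiers (UniProt accessions, Entrez ids, ...) to HGNC
#' symbols. TSV with header `namespace<TAB>id<TAB>symbol`; duplicate
#' (namespace, id) keys are an error.
#'
#' @param path TSV path.
#' @return Data frame of class `symbol_map` (namespace, id, symbol).
#' @export
read_symbol_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("namespace", "id", "symbol") %in% names(tab)))
  key <- paste(tab$namespace, tab$id, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (namespace, id) keys in symbol map: ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tab$symbol)))
    stop("empty HGNC symbols in symbol map", call. = FALSE)
  class(tab) <- c("symbol_map", "data.frame")
  tab
}

#' Normalize pathway identifiers to HGNC symbols
#'
#' Protein nodes whose symbol matches a `namespace:id` (or bare `id`) row of
#' the map are renamed to the mapped HGNC symbol; edges are rewired; two
#' source nodes mapping to one symbol coalesce into a single node (their
#' pathway memberships union, duplicate edges collapse, and no self-loop is
#' created unless present in the source). Unmapped foreign-looking ids are
#' kept under an `unmapped:` prefix and counted in the returned attribute
#' `n_unmapped`.
#'
#' @param net A [pathway_network()].
#' @param map A `symbol_map` data frame ([read_symbol_map()]), or `NULL`
#'   for the identity mapping.
#' @return A [pathway_network()].
#' @export
normalize_identifiers <- function(net, map = NULL) {
  stopifnot(inherits(net, "pathway_network"))
  if (is.null(map) || nrow(map) == 0) return(net)
  lut <- structure(map$symbol, names = toupper(map$id))
  nodes <- net$nodes
  is_p <- nodes$entity_class == "protein"
  old <- nodes$symbol
  hit <- is_p & old %in% names(lut)
  new <- old
  new[hit] <- toupper(unname(lut[old[hit]]))
  ## foreign-looking unmapped ids (declared namespaces only, e.g. UniProt
  ## accessions P?????) are flagged rather than silently treated as symbols
  looks_foreign <- is_p & !hit &
    grepl("^[OPQ][0-9][A-Z0-9]{3}[0-9]$", old)
  new[looks_foreign] <- paste0("unmapped:", old[looks_foreign])
  n_unmapped <- sum(looks_foreign)
  remap <- structure(new, names = old)
  nodes$symbol <- new
  ## coalesce nodes that now share a symbol
  agg <- lapply(split(seq_len(nrow(nodes)), nodes$symbol), function(ix) {
    data.frame(symbol = nodes$symbol[ix[1]],
               entity_class = nodes$entity_class[ix[1]],
               xrefs = paste(csort(unique(c(
                 strsplit(paste(nodes$xrefs[ix], collapse = ";"),
                          ";")[[1]],
                 old[ix][old[ix] != nodes$symbol[ix[1]]]))),
                 collapse = ";"),
               pathways = paste(csort(unique(unlist(
                 strsplit(nodes$pathways[ix], ";")))), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  nodes2 <- do.call(rbind, agg)
  nodes2$xrefs <- sub("^;", "", nodes2$xrefs)
  edges <- net$edges
  if (nrow(edges)) {
    was_loop <- edges$source == edges$target
    edges$source <- unname(remap[edges$source])
    edges$target <- unname(remap[edges$target])
    ## a self-loop created purely by node coalescence is an artifact, not
    ## an interaction; loops present in the source are kept
    edges <- edges[!(edges$source == edges$target & !was_loop), ,
                   drop = FALSE]
    edges <- unique(edges)
  }
  out <- pathway_network(net$pathway_ids, nodes2, edges)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Combine pathway networks
#'
#' Union of nodes by symbol (pathway memberships merged) and of edges by
#' (source, interaction, target); pathway identity lists are concatenated.
#' Associative and order-invariant on node and edge sets.
#'
#' @param nets List of [pathway_network()] objects.
#' @return A [pathway_network()].
#' @export
pw_combine <- function(nets) {
  stopifnot(is.list(nets), all(vapply(nets, inherits, logical(1),
                                      what = "pathway_network")))
  if (length(nets) == 0) return(pathway_network())
  ids <- unique(do.call(rbind, lapply(nets, `[[`, "pathway_ids")))
  rownames(ids) <- NULL
  nodes_all <- do.call(rbind, lapply(nets, `[[`, "nodes"))
  agg <- lapply(split(seq_len(nrow(nodes_all)), nodes_all$symbol),
                function(ix) {
    cls <- nodes_all$entity_class[ix]
    data.frame(
      symbol = nodes_all$symbol[ix[1]],
      entity_class = if ("protein" %in% cls) "protein" else cls[1],
      xrefs = paste(csort(unique(setdiff(unlist(
        strsplit(nodes_all$xrefs[ix], ";")), ""))), collapse = ";"),
      pathways = paste(csort(unique(setdiff(unlist(
        strsplit(nodes_all$pathways[ix], ";")), ""))), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  nodes <- do.call(rbind, agg)
  edges <- unique(do.call(rbind, lapply(nets, `[[`, "edges")))
  pathway_network(ids, nodes, edges)
}
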