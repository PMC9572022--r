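#' Evidence-carrying knowledge graph
#'
#' The graph compiled from curated BEL documents is a typed *multigraph*:
#' nodes are canonical BEL terms (see [term_key()]), and every curated
#' statement contributes its own edge, so two statements asserting the same
#' triple from different publications remain two edges — edge totals are
#' evidence-level counts. Complex and reaction nodes additionally induce
#' `hasComponent` edges to each component node; induced edges are tagged and
#' excluded from evidence counting.
#'
#' @name coag_kg
#' @keywords internal
NULL

.empty_edges <- function() {
  data.frame(subject = character(0), relation = character(0),
             object = character(0), citation = character(0),
             evidence = character(0), induced = logical(0),
             annotations = I(list()), stringsAsFactors = FALSE)
}

.new_kg <- function(terms, node_type, edges, provenance) {
  ord <- if (length(terms)) corder(names(terms)) else integer(0)
  structure(list(terms = terms[ord], node_type = node_type[names(terms)[ord]],
                 edges = edges, provenance = provenance),
            class = "coag_kg")
}

#' @export
print.coag_kg <- function(x, ...) {
  s <- kg_stats(x)
  cat("<coag_kg> ", s$n_nodes, " nodes (", s$n_by_type[["protein"]],
      " proteins), ", s$n_edges, " edges, ", s$n_citations,
      " citations\n", sep = "")
  if (length(x$provenance))
    cat("  sources: ", paste(x$provenance, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## register a term (and, recursively, its components) in the accumulators;
## returns updated env-free lists
.register_term <- function(term, terms, node_type, induced) {
  key <- term_key(term)
  if (is.null(terms[[key]])) {
    t0 <- term
    t0$activity <- FALSE          # activity is an edge aspect, not identity
    terms[[key]] <- t0
    node_type[[key]] <- term$fn
  }
  if (term$fn %in% c("complex", "reaction")) {
    for (comp in term$components) {
      res <- .register_term(comp, terms, node_type, induced)
      terms <- res$terms; node_type <- res$node_type; induced <- res$induced
      induced[[paste0(key, ">", term_key(comp))]] <-
        c(key, term_key(comp))
    }
  }
  list(terms = terms, node_type = node_type, induced = induced)
}

#' Compile BEL documents into a knowledge graph
#'
#' One node per distinct canonical term key; one edge per statement, plus
#' induced `hasComponent` edges from each composite node to its components
#' (deduplicated). Statements touching an excluded entity (see
#' [normalize_term()]) are skipped and counted. The node table is sorted by
#' canonical key, so the result is invariant under statement order.
#'
#' @param docs A `bel_document` or list of them.
#' @param normalize Apply [normalize_term()] to subjects and objects first
#'   (default `TRUE`).
#' @return A `coag_kg` object.
#' @examples
#' doc <- parse_document("a(CHEBI:heme) -> p(HGNC:F3)")
#' kg_compile(doc)
#' @export
kg_compile <- function(docs, normalize = TRUE) {
  if (inherits(docs, "bel_document")) docs <- list(docs)
  terms <- list(); node_type <- list(); induced <- list()
  rows <- list()
  n_skipped <- 0L
  provenance <- character(0)
  for (doc in docs) {
    stopifnot(inherits(doc, "bel_document"))
    if (nzchar(doc$header$name))
      provenance <- c(provenance, doc$header$name)
    for (stmt in doc$statements) {
      subj <- stmt$subject; obj <- stmt$object
      if (normalize) {
        subj <- normalize_term(subj)
        obj <- normalize_term(obj)
        if (is_excluded(subj) || is_excluded(obj)) {
          n_skipped <- n_skipped + 1L
          next
        }
      }
      for (t in list(subj, obj)) {
        res <- .register_term(t, terms, node_type, induced)
        terms <- res$terms; node_type <- res$node_type; induced <- res$induced
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = term_key(subj), relation = stmt$relation,
        object = term_key(obj), citation = stmt$citation,
        evidence = stmt$evidence, induced = FALSE,
        annotations = I(list(stmt$annotations)), stringsAsFactors = FALSE)
    }
  }
  ind_rows <- lapply(induced, function(p) data.frame(
    subject = p[1], relation = "hasComponent", object = p[2],
    citation = "NA", evidence = "", induced = TRUE,
    annotations = I(list(annotation_set())), stringsAsFactors = FALSE))
  edges <- do.call(rbind, c(rows, ind_rows[csort(names(ind_rows))],
                            list(.empty_edges())))
  node_type <- unlist(node_type)
  if (is.null(node_type)) node_type <- character(0)
  kg <- .new_kg(terms, node_type, edges, provenance)
  attr(kg, "n_skipped") <- n_skipped
  if (n_skipped > 0)
    message(n_skipped, " statement(s) referencing excluded entities skipped")
  kg
}

## dedup key for non-induced edges: evidence-level identity
.edge_dedup_key <- function(edges) {
  paste(edges$subject, edges$relation, edges$object, edges$citation,
        edges$evidence, edges$induced, sep = "\r")
}

#' Merge knowledge graphs
#'
#' Node set is the union by canonical key (a key collision with differing
#' node types is an error); edges are deduplicated on the full
#' evidence-level key (subject, relation, object, citation, evidence), so
#' `kg_merge(list(g, g))` equals `g` and merging with the empty graph is the
#' identity. Provenance lists are concatenated.
#'
#' @param graphs List of `coag_kg` objects.
#' @return A `coag_kg`.
#' @export
kg_merge <- function(graphs) {
  stopifnot(is.list(graphs), all(vapply(graphs, inherits, logical(1),
                                        what = "coag_kg")))
  if (length(graphs) == 0) return(kg_compile(list()))
  terms <- list(); node_type <- list()
  for (g in graphs) {
    for (key in names(g$terms)) {
      if (is.null(terms[[key]])) {
        terms[[key]] <- g$terms[[key]]
        node_type[[key]] <- g$node_type[[key]]
      } else if (!identical(node_type[[key]], unname(g$node_type[[key]]))) {
        stop(sprintf("node-type conflict for key '%s': %s vs %s", key,
                     node_type[[key]], g$node_type[[key]]), call. = FALSE)
      }
    }
  }
  edges <- do.call(rbind, c(lapply(graphs, `[[`, "edges"),
                            list(.empty_edges())))
  edges <- edges[!duplicated(.edge_dedup_key(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  .new_kg(terms, unlist(node_type),
          edges, unique(unlist(lapply(graphs, `[[`, "provenance"))))
}

#' Knowledge-graph summary statistics
#'
#' Node, edge, per-node-type and distinct-citation counts. Induced
#' `hasComponent` edges are included in the edge total by default
#' (`include_induced = FALSE` reports statement-level edges only); both
#' conventions are found in deposited graphs.
#'
#' @param kg A `coag_kg`.
#' @param include_induced Count induced `hasComponent` edges in `n_edges`.
#' @return A `kg_stats` list: `n_nodes`, `n_edges`, `n_by_type` (named
#'   vector over the nine node functions), `n_proteins`, `n_citations`.
#' @export
kg_stats <- function(kg, include_induced = TRUE) {
  stopifnot(inherits(kg, "coag_kg"))
  edges <- kg$edges
  if (!include_induced) edges <- edges[!edges$induced, , drop = FALSE]
  by_type <- table(factor(unname(kg$node_type), levels = BEL_FUNCTIONS))
  by_type <- structure(as.integer(by_type), names = names(by_type))
  cits <- setdiff(unique(edges$citation), "NA")
  structure(list(n_nodes = length(kg$terms), n_edges = nrow(edges),
                 n_by_type = by_type,
                 n_proteins = by_type[["protein"]],
                 n_citations = length(cits)),
            class = "kg_stats")
}

#' @export
print.kg_stats <- function(x, ...) {
  cat("nodes:", x$n_nodes, " edges:", x$n_edges,
      " proteins:", x$n_proteins, " citations:", x$n_citations, "\n")
  nz <- x$n_by_type[x$n_by_type > 0]
  if (length(nz))
    cat(paste(sprintf("  %s: %d", names(nz), nz), collapse = "\n"), "\n")
  invisible(x)
}

#' Evidence abundance of a node
#'
#' Number of curated statements (edges, any direction, excluding induced
#' `hasComponent` edges) incident to a node. This is the quantity node
#' sizes are scaled by in the crosstalk overlays: heavily studied entities
#' draw large nodes.
#'
#' @param kg A `coag_kg`.
#' @param node_key Canonical key of an existing node.
#' @return Non-negative integer count.
#' @export
evidence_count <- function(kg, node_key) {
  stopifnot(inherits(kg, "coag_kg"))
  if (!node_key %in% names(kg$terms))
    stop(sprintf("unknown node key '%s'", node_key), call. = FALSE)
  e <- kg$edges[!kg$edges$induced, , drop = FALSE]
  sum(e$subject == node_key) + sum(e$object == node_key)
}

## ---- exports ---------------------------------------------------------------

#' Node and edge tables of a knowledge graph
#'
#' @param kg A `coag_kg`.
#' @return `kg_nodes()`: data frame (key, type, namespace, name, label);
#'   `kg_edges()`: the edge data frame without the annotation list-column
#'   (annotations serialized to compact JSON strings).
#' @export
kg_nodes <- function(kg) {
  stopifnot(inherits(kg, "coag_kg"))
  keys <- names(kg$terms)
  data.frame(
    key = keys,
    type = unname(kg$node_type[keys]),
    namespace = vapply(kg$terms, function(t) t$namespace, character(1),
                       USE.NAMES = FALSE),
    name = vapply(kg$terms, function(t) t$name, character(1),
                  USE.NAMES = FALSE),
    label = vapply(kg$terms, serialize_term, character(1),
                   USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

.ann_json <- function(ann) {
  a <- unclass(ann)
  a <- a[!vapply(a, function(v)
    (length(v) == 1L && is.na(v)) || length(v) == 0L, logical(1))]
  jsonlite::toJSON(a, auto_unbox = TRUE)
}

#' @rdname kg_nodes
#' @export
kg_edges <- function(kg) {
  stopifnot(inherits(kg, "coag_kg"))
  e <- kg$edges
  out <- e[setdiff(names(e), "annotations")]
  out$annotations <- vapply(e$annotations, .ann_json, character(1))
  rownames(out) <- NULL
  out
}

#' Read/write a knowledge graph as canonical node-link JSON
#'
#' Deterministic export (nodes sorted by key, fixed field order) so that
#' repeated writes of the same graph are byte-identical.
#'
#' @param kg A `coag_kg`.
#' @param path File path.
#' @return `write_kg_json()`: `path` invisibly; `read_kg_json()`: a
#'   `coag_kg`.
#' @export
write_kg_json <- function(kg, path) {
  obj <- list(
    directed = TRUE, multigraph = TRUE,
    provenance = as.list(kg$provenance),
    nodes = kg_nodes(kg),
    links = kg_edges(kg))
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_kg_json
#' @export
read_kg_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nodes <- obj$nodes
  terms <- lapply(nodes$label, parse_term)
  names(terms) <- nodes$key
  node_type <- structure(nodes$type, names = nodes$key)
  links <- obj$links
  if (is.null(links) || length(links) == 0 || NROW(links) == 0) {
    edges <- .empty_edges()
  } else {
    anns <- lapply(links$annotations, function(js) {
      a <- jsonlite::fromJSON(js)
      do.call(annotation_set, a)
    })
    edges <- data.frame(subject = links$subject, relation = links$relation,
                        object = links$object, citation = links$citation,
                        evidence = links$evidence, induced = links$induced,
                        annotations = I(anns), stringsAsFactors = FALSE)
  }
  .new_kg(terms, node_type, edges, unlist(obj$provenance))
}

#' Export a knowledge graph to GraphML
#'
#' Converts the multigraph to an [igraph::graph_from_data_frame()] object
#' (node attributes: type, namespace, name, label; edge attributes:
#' relation, citation, induced) and writes GraphML for use in external
#' network viewers.
#'
#' @param kg A `coag_kg`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_kg_graphml <- function(kg, path) {
  nodes <- kg_nodes(kg)
  e <- kg$edges
  if (nrow(e) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(nodes$key)
  } else {
    g <- igraph::graph_from_data_frame(
      e[c("subject", "object", "relation", "citation", "induced")],
      directed = TRUE, vertices = nodes)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a knowledge graph to an igraph object
#' @param kg A `coag_kg`.
#' @return A directed [igraph::graph] with node/edge attributes.
#' @export
kg_to_igraph <- function(kg) {
  nodes <- kg_nodes(kg)
  e <- kg$edges
  if (nrow(e) == 0)
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(nodes$key))
  igraph::graph_from_data_frame(
    e[c("subject", "object", "relation", "citation", "evidence", "induced")],
    directed = TRUE, vertices = nodes)
}
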