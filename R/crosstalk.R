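#' Entity alias table
#'
#' Curated common-name aliases used when matching knowledge-graph entities
#' to pathway nodes: the literature mixes gene symbols and trivial names
#' freely (APC for activated protein C = PROC, thrombin = F2, tissue
#' factor = F3, GPVI = GP6, ...). Aliases are case-folded; the table is an
#' editable TSV (`alias`, `symbol`) bundled under `inst/extdata/`.
#'
#' @param path Optional TSV path; default reads the bundled table.
#' @return Named character vector: case-folded alias -> HGNC symbol.
#' @export
entity_aliases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "entity_aliases.tsv", package = "coagkg")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(toupper(tab$symbol), names = tolower(tab$alias))
}

## leaf protein symbols of a term tree (complex components contribute)
.term_protein_symbols <- function(term) {
  if (term$fn %in% c("complex", "reaction"))
    unique(unlist(lapply(term$components, .term_protein_symbols)))
  else if (term$fn == "protein") toupper(term$name)
  else character(0)
}

## overlap-eligible symbols of a KG: list(proteins, named)
.kg_symbols <- function(kg, aliases) {
  proteins <- character(0); named <- character(0)
  for (key in names(kg$terms)) {
    term <- kg$terms[[key]]
    proteins <- c(proteins, .term_protein_symbols(term))
    if (term$fn %in% c("abundance", "bioProcess", "pathology")) {
      nm <- tolower(term$name)
      if (nm %in% names(aliases)) proteins <- c(proteins, aliases[[nm]])
      else named <- c(named, nm)
    }
  }
  list(proteins = csort(unique(proteins)), named = csort(unique(named)))
}

.pw_symbols <- function(net, aliases) {
  nodes <- net$nodes
  is_p <- nodes$entity_class == "protein" &
    !startsWith(nodes$symbol, "unmapped:")
  proteins <- toupper(nodes$symbol[is_p])
  named <- tolower(nodes$symbol[!is_p & !startsWith(nodes$symbol,
                                                   "unmapped:")])
  hit <- named %in% names(aliases)
  proteins <- c(proteins, unname(aliases[named[hit]]))
  list(proteins = csort(unique(proteins)),
       named = csort(unique(named[!hit])))
}

## node keys of a KG that involve a protein symbol or named entity
.symbol_node_keys <- function(kg, symbol, protein = TRUE) {
  hits <- vapply(kg$terms, function(term) {
    if (protein) symbol %in% .term_protein_symbols(term)
    else term$fn %in% c("abundance", "bioProcess", "pathology") &&
      tolower(term$name) == symbol
  }, logical(1))
  names(kg$terms)[hits]
}

#' Superimpose a knowledge graph on a pathway network
#'
#' The crosstalk engine: intersects the overlap-eligible symbols of the
#' curated knowledge graph (proteins by HGNC symbol — complex components
#' included, so a heme-bound factor counts; abundances, processes and
#' pathologies by case-folded name, with common-name aliases resolved to
#' symbols) with the pathway network's symbols, partitioning the union into
#' `common`, `kg_only` and `pathway_only`. Node sizes reflect evidence
#' abundance in the underlying curated statements (`1 + incident
#' statements`; pathway-only nodes take the floor size 1). When a
#' localization table and compartment are given, the protein sets on both
#' sides are restricted to that compartment first.
#'
#' @param kg A `coag_kg`.
#' @param net A [pathway_network()].
#' @param loc Optional `localization_table` ([build_localization()]).
#' @param compartment Optional `"extracellular"`, `"membrane"` or
#'   `"intracellular"`; requires `loc`.
#' @param aliases Alias vector, see [entity_aliases()].
#' @param universe_size Optional protein universe size; when given the
#'   hypergeometric overlap probability is computed (see [overlap_test()]).
#' @return A `crosstalk_result`: `compartment`, sorted symbol vectors
#'   `common` / `kg_only` / `pathway_only`, `node_sizes`, protein-overlap
#'   `counts`, `overlap_p`, `universe_size`, and per-symbol
#'   `pathway_membership`.
#' @export
superimpose <- function(kg, net, loc = NULL, compartment = NULL,
                        aliases = entity_aliases(), universe_size = NULL) {
  stopifnot(inherits(kg, "coag_kg"), inherits(net, "pathway_network"))
  if (!is.null(compartment)) {
    if (is.null(loc))
      stop("a compartment restriction requires a localization table",
           call. = FALSE)
    compartment <- match.arg(compartment, COMPARTMENTS)
  }
  ks <- .kg_symbols(kg, aliases)
  ps <- .pw_symbols(net, aliases)
  if (!is.null(compartment)) {
    allowed <- partition_compartments(
      union(ks$proteins, ps$proteins), loc)[[compartment]]
    ks$proteins <- intersect(ks$proteins, allowed)
    ps$proteins <- intersect(ps$proteins, allowed)
  }
  common_p <- intersect(ks$proteins, ps$proteins)
  common_n <- intersect(ks$named, ps$named)
  common <- csort(c(common_p, common_n))
  kg_only <- csort(c(setdiff(ks$proteins, ps$proteins),
                    setdiff(ks$named, ps$named)))
  pathway_only <- csort(c(setdiff(ps$proteins, ks$proteins),
                         setdiff(ps$named, ks$named)))
  all_syms <- c(common, kg_only, pathway_only)
  sizes <- vapply(all_syms, function(s) {
    keys <- .symbol_node_keys(kg, s,
                              protein = s %in% c(ks$proteins, ps$proteins))
    if (length(keys) == 0) return(1)
    e <- kg$edges[!kg$edges$induced, , drop = FALSE]
    1 + sum(e$subject %in% keys | e$object %in% keys)
  }, numeric(1))
  membership <- .pw_membership(net, ps, aliases)
  res <- structure(
    list(compartment = if (is.null(compartment)) "all" else compartment,
         common = common, kg_only = kg_only, pathway_only = pathway_only,
         node_sizes = sizes,
         counts = c(kg = length(ks$proteins), pathway = length(ps$proteins),
                    common = length(common_p)),
         overlap_p = NULL, universe_size = universe_size,
         pathway_membership = membership),
    class = "crosstalk_result")
  if (!is.null(universe_size)) res$overlap_p <- overlap_test(res)
  res
}

## pathway membership per overlap symbol (accession sets)
.pw_membership <- function(net, ps, aliases) {
  nodes <- net$nodes
  out <- list()
  for (i in seq_len(nrow(nodes))) {
    s <- nodes$symbol[i]
    if (startsWith(s, "unmapped:")) next
    key <- if (nodes$entity_class[i] == "protein") toupper(s) else {
      lo <- tolower(s)
      if (lo %in% names(aliases)) unname(aliases[[lo]]) else lo
    }
    accs <- setdiff(strsplit(nodes$pathways[i], ";")[[1]], "")
    out[[key]] <- csort(unique(c(out[[key]], accs)))
  }
  out
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat("<crosstalk_result> compartment: ", x$compartment, "\n",
      "  common (", length(x$common), "): ",
      paste(x$common, collapse = ", "), "\n",
      "  kg-only: ", length(x$kg_only),
      "  pathway-only: ", length(x$pathway_only), "\n", sep = "")
  if (!is.null(x$overlap_p))
    cat(sprintf("  overlap p = %.3g (universe %d)\n", x$overlap_p,
                x$universe_size))
  invisible(x)
}

#' Hypergeometric overlap probability
#'
#' Upper-tail probability of seeing at least the observed number of common
#' proteins when drawing the pathway's protein set from a finite universe
#' containing the knowledge graph's proteins as marked items:
#' `P(X >= k)` with `X ~ Hypergeometric(universe, |KG|, |pathway|)`.
#' Zero overlap therefore gives exactly 1.
#'
#' @param result A `crosstalk_result` from [superimpose()].
#' @param universe_size Universe size; defaults to the one stored in
#'   `result`.
#' @return A probability in `[0, 1]`.
#' @export
overlap_test <- function(result, universe_size = NULL) {
  stopifnot(inherits(result, "crosstalk_result"))
  if (is.null(universe_size)) universe_size <- result$universe_size
  if (is.null(universe_size))
    stop("universe_size required", call. = FALSE)
  K <- result$counts[["kg"]]; n <- result$counts[["pathway"]]
  k <- result$counts[["common"]]
  if (universe_size < K || universe_size < n || k > min(K, n) ||
      k < max(0L, K + n - universe_size))
    stop(sprintf(paste0("infeasible hypergeometric counts: |KG|=%d, ",
                        "|pathway|=%d, |common|=%d, universe=%d"),
                 K, n, k, universe_size), call. = FALSE)
  stats::phyper(k - 1, K, universe_size - K, n, lower.tail = FALSE)
}

#' Knowledge-gap report
#'
#' Lists the pathway-only symbols — database pathway members with no
#' curated heme relation — as candidate targets, with the pathways they
#' appear in and an optional literature-screening status
#' (`not_screened`, `screened_negative`,
#' `screened_positive_external_celltype`) supplied as a curated table
#' (manual screening output is an input here, never computed). Entries
#' screened positive in another cell type are appended even when absent
#' from the pathway-only set. Rows are ordered by pathway count
#' (descending) then symbol.
#'
#' @param result A `crosstalk_result`.
#' @param screened Optional data frame (`symbol`, `status`) or TSV path.
#' @return Data frame of class `gap_report`: `symbol`, `pathways`,
#'   `n_pathways`, `literature_status`.
#' @export
gap_report <- function(result, screened = NULL) {
  stopifnot(inherits(result, "crosstalk_result"))
  if (is.character(screened))
    screened <- utils::read.delim(screened, stringsAsFactors = FALSE)
  statuses <- c("not_screened", "screened_negative",
                "screened_positive_external_celltype")
  syms <- result$pathway_only
  status <- rep("not_screened", length(syms))
  names(status) <- syms
  if (!is.null(screened)) {
    stopifnot(all(c("symbol", "status") %in% names(screened)),
              all(screened$status %in% statuses))
    extra <- setdiff(
      screened$symbol[screened$status ==
                        "screened_positive_external_celltype"], syms)
    syms <- c(syms, extra)
    status <- c(status, structure(rep("not_screened", length(extra)),
                                  names = extra))
    hit <- intersect(screened$symbol, syms)
    status[hit] <- screened$status[match(hit, screened$symbol)]
  }
  memb <- result$pathway_membership[syms]
  pw <- vapply(memb, function(v)
    if (is.null(v)) "" else paste(v, collapse = ";"), character(1))
  n_pw <- vapply(memb, function(v) if (is.null(v)) 0L else length(v),
                 integer(1))
  out <- data.frame(symbol = syms, pathways = unname(pw),
                    n_pathways = unname(n_pw),
                    literature_status = unname(status[syms]),
                    stringsAsFactors = FALSE)
  out <- out[corder(-out$n_pathways, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gap_report", "data.frame")
  out
}

#' Export crosstalk results
#'
#' Writes `overlap.tsv` (one row per symbol: membership class, compartment
#' labels, evidence size, pathway memberships), `gaps.tsv` (the
#' [gap_report()]) and `overlay.json` (node-link JSON with membership
#' attributes, suitable for rendering network overlays). Output is
#' deterministic: identical results produce byte-identical files.
#'
#' @param result A `crosstalk_result`.
#' @param dir Output directory (created if needed).
#' @param loc Optional `localization_table` used to annotate compartment
#'   labels per symbol.
#' @param screened Optional screening-status input passed to
#'   [gap_report()].
#' @return Named character vector of the written paths, invisibly.
#' @export
export_report <- function(result, dir, loc = NULL, screened = NULL) {
  stopifnot(inherits(result, "crosstalk_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cls <- c(structure(rep("common", length(result$common)),
                     names = result$common),
           structure(rep("kg_only", length(result$kg_only)),
                     names = result$kg_only),
           structure(rep("pathway_only", length(result$pathway_only)),
                     names = result$pathway_only))
  syms <- csort(names(cls))
  comp <- vapply(syms, function(s) {
    if (is.null(loc)) return("")
    paste(loc$labels[[toupper(s)]], collapse = ";")
  }, character(1))
  memb <- vapply(syms, function(s) {
    v <- result$pathway_membership[[s]]
    if (is.null(v)) "" else paste(v, collapse = ";")
  }, character(1))
  tab <- data.frame(symbol = syms, class = unname(cls[syms]),
                    compartments = unname(comp),
                    size = unname(result$node_sizes[syms]),
                    pathways = unname(memb), stringsAsFactors = FALSE)
  overlap_path <- file.path(dir, "overlap.tsv")
  utils::write.table(tab, overlap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gaps_path <- file.path(dir, "gaps.tsv")
  utils::write.table(gap_report(result, screened), gaps_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  overlay_path <- file.path(dir, "overlay.json")
  obj <- list(compartment = result$compartment,
              universe_size = result$universe_size,
              overlap_p = result$overlap_p,
              counts = as.list(result$counts),
              nodes = tab)
  writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, null = "null"),
             overlay_path, useBytes = TRUE)
  invisible(c(overlap = overlap_path, gaps = gaps_path,
              overlay = overlay_path))
}
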