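#' Simulation configuration
#'
#' Controls the synthetic study generator, which emulates the statistical
#' structure the crosstalk analysis assumes: a heme-centric curated corpus
#' (a hub entity touching most statements), database pathways sharing a
#' controlled fraction of proteins with the corpus, and GO annotations
#' assigning each protein to planted compartments. Defaults mirror the
#' scale of the curated heme--thrombosis corpus: 47 proteins, 426
#' statements, 6 pathways, and compartment weights that reproduce the
#' 22/10/18 extracellular/membrane/intracellular split in expectation.
#'
#' @param n_proteins Number of distinct proteins in the corpus vocabulary.
#' @param n_statements Number of curated statements.
#' @param relation_weights Named probability vector over the six relations.
#' @param p_complex Probability a heme statement's subject is a
#'   heme--protein complex (binding-style curation).
#' @param hub_fraction Fraction of statements whose subject involves heme.
#' @param annotation_fill Probability each context annotation field is
#'   populated.
#' @param n_pathways Number of synthetic pathway exports.
#' @param pathway_size Integer range `c(min, max)` of pathway sizes
#'   (min >= 2 so every member is an edge endpoint).
#' @param overlap_fraction Fraction of each pathway's members planted from
#'   the corpus vocabulary.
#' @param compartment_weights Named probability vector over
#'   extracellular/membrane/intracellular.
#' @param multilabel_p Probability a protein carries a second compartment
#'   label.
#' @param seed Integer seed of the single pseudo-random stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 47, n_statements = 426,
                       relation_weights = c(
                         increases = 0.30, directlyIncreases = 0.20,
                         decreases = 0.15, directlyDecreases = 0.10,
                         association = 0.15, regulates = 0.10),
                       p_complex = 0.15, hub_fraction = 0.70,
                       annotation_fill = 0.40,
                       n_pathways = 6, pathway_size = c(10, 30),
                       overlap_fraction = 0.30,
                       compartment_weights = c(extracellular = 0.44,
                                               membrane = 0.20,
                                               intracellular = 0.36),
                       multilabel_p = 0.06, seed = 1L) {
  stopifnot(n_proteins > 0, n_statements >= 0,
            length(pathway_size) == 2, pathway_size[1] >= 2,
            pathway_size[1] <= pathway_size[2], n_pathways >= 0)
  probs <- c(p_complex, hub_fraction, annotation_fill, overlap_fraction,
             multilabel_p)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!setequal(names(relation_weights), BEL_RELATIONS) ||
      abs(sum(relation_weights) - 1) > 1e-8)
    stop("relation_weights must cover the six relations and sum to 1",
         call. = FALSE)
  if (!setequal(names(compartment_weights), COMPARTMENTS) ||
      abs(sum(compartment_weights) - 1) > 1e-8)
    stop("compartment_weights must cover the three compartments and sum ",
         "to 1", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_statements = as.integer(n_statements),
                 relation_weights = relation_weights[BEL_RELATIONS],
                 p_complex = p_complex, hub_fraction = hub_fraction,
                 annotation_fill = annotation_fill,
                 n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 overlap_fraction = overlap_fraction,
                 compartment_weights = compartment_weights[COMPARTMENTS],
                 multilabel_p = multilabel_p, seed = as.integer(seed)),
            class = "sim_config")
}

## coagulation-flavored protein vocabulary; synthetic symbols beyond it
COAG_VOCAB <- c(
  "F2", "F3", "F5", "F7", "F8", "F9", "F10", "F11", "F12", "F13A1",
  "VWF", "PROC", "PROS1", "KLKB1", "KNG1", "FGA", "FGB", "FGG", "PLG",
  "SERPINC1", "SERPINE1", "THBD", "GP6", "GP1BA", "ITGA2B", "ITGB3",
  "SYK", "AKT1", "NOS3", "PLCG2", "PRKCA", "SRC", "MYH9", "MAPK1",
  "PIK3CA", "TLR4", "CLEC1B", "SELP", "SELE", "ICAM1", "VCAM1", "MMP9",
  "HP", "HPX", "ALB", "C3", "NLRP3")

.sim_vocab <- function(n) {
  if (n <= length(COAG_VOCAB)) COAG_VOCAB[seq_len(n)]
  else c(COAG_VOCAB, sprintf("SYNP%03d", seq_len(n - length(COAG_VOCAB))))
}

.process_pool <- list(
  list(fn = "bioProcess", ns = "GO", name = "blood coagulation"),
  list(fn = "bioProcess", ns = "GO", name = "platelet activation"),
  list(fn = "bioProcess", ns = "GO", name = "platelet aggregation"),
  list(fn = "bioProcess", ns = "GO", name = "platelet degranulation"),
  list(fn = "bioProcess", ns = "GO", name = "fibrinolysis"),
  list(fn = "pathology", ns = "MESH", name = "Thrombosis"),
  list(fn = "pathology", ns = "MESH", name = "Hemolysis"))

.heme <- function() bel_term("abundance", "CHEBI", "heme")

#' Generate a synthetic curated corpus
#'
#' Draws `n_statements` statements over a coagulation-flavored vocabulary
#' with heme as the hub entity in `hub_fraction` of them (plain heme
#' subject or, with probability `p_complex`, a heme--protein complex),
#' cycling through the vocabulary so every protein appears. Context
#' annotations are filled with probability `annotation_fill`. Consumes the
#' config's seeded stream from the start; the planted compartment labels of
#' every protein are drawn at the end of the corpus stage so the corpus
#' bytes do not depend on later stages.
#'
#' @param cfg A [sim_config()].
#' @return List with `documents` (list of one `bel_document`) and `truth`
#'   (vocabulary, per-protein compartment labels, planted counts).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  vocab <- .sim_vocab(cfg$n_proteins)
  statements <- vector("list", cfg$n_statements)
  used <- character(0)
  for (i in seq_len(cfg$n_statements)) {
    prot <- vocab[(i - 1L) %% cfg$n_proteins + 1L]
    used <- union(used, prot)
    rel <- sample(names(cfg$relation_weights), 1L,
                  prob = cfg$relation_weights)
    pterm <- bel_term("protein", "HGNC", prot)
    is_hub <- stats::runif(1) < cfg$hub_fraction
    kd <- NULL
    if (is_hub) {
      if (stats::runif(1) < cfg$p_complex) {
        subj <- bel_term("complex", components = list(.heme(), pterm))
        if (stats::runif(1) < 0.5) {
          obj <- pterm; obj$activity <- TRUE
        } else obj <- .rand_process()
        if (stats::runif(1) < cfg$annotation_fill)
          kd <- list(value = sample(c(1.9, 12.7, 29.4, 400, 3300), 1L),
                     unit = "nM")
      } else {
        subj <- .heme()
        obj <- if (stats::runif(1) < 0.8) pterm else {
          o <- pterm; o$activity <- TRUE; o
        }
      }
    } else {
      subj <- pterm
      obj <- .rand_process()
    }
    ann <- .rand_annotations(cfg, kd)
    statements[[i]] <- bel_statement(
      subj, rel, obj,
      citation = sprintf("%d", sample(10000000:99999999, 1L)),
      evidence = sprintf("Synthetic evidence sentence %04d.", i),
      annotations = ann)
  }
  ## planted compartment labels, drawn last in the corpus stage
  labels <- lapply(seq_along(vocab), function(i) {
    first <- sample(COMPARTMENTS, 1L, prob = cfg$compartment_weights)
    if (stats::runif(1) < cfg$multilabel_p)
      csort(c(first, sample(setdiff(COMPARTMENTS, first), 1L)))
    else first
  })
  names(labels) <- vocab
  doc <- structure(list(
    statements = statements,
    header = list(name = "synthetic_corpus", version = "1.0",
                  namespaces = c("HGNC", "CHEBI", "GO", "MESH", "TEXT")),
    errors = data.frame(line = integer(0), message = character(0)),
    line_counts = c(statements = length(statements), errors = 0L,
                    other = 0L)), class = "bel_document")
  truth <- list(vocabulary = vocab, used = csort(used),
                n_proteins = length(used),
                n_statements = cfg$n_statements,
                compartments = labels,
                compartment_sizes = vapply(COMPARTMENTS, function(cmp)
                  sum(vapply(labels, function(l) cmp %in% l, logical(1))),
                  integer(1)))
  list(documents = list(doc), truth = truth)
}

.rand_process <- function() {
  p <- .process_pool[[sample(length(.process_pool), 1L)]]
  bel_term(p$fn, p$ns, p$name)
}

.rand_annotations <- function(cfg, kd = NULL) {
  fill <- function() stats::runif(1) < cfg$annotation_fill
  ann <- annotation_set()
  if (fill()) ann$cell_type <- sample(c("endothelial cell", "platelet",
                                        "neutrophil", "monocyte"), 1L)
  if (fill()) ann$species <- sample(c("9606", "10090"), 1L)
  if (fill()) ann$setting <- sample(c("in_vitro", "in_vivo", "ex_vivo"), 1L)
  if (fill()) {
    ann$dose_value <- sample(c(2.5, 10, 20, 30, 50, 100), 1L)
    ann$dose_unit <- "\u00b5M"
    ann$dose_qualifier <- sample(c("exact", "up_to"), 1L)
  }
  if (fill()) ann$route <- sample(c("incubation", "intravenous",
                                    "retroorbital"), 1L)
  if (!is.null(kd)) { ann$kd_value <- kd$value; ann$kd_unit <- kd$unit }
  ann
}

#' Generate synthetic pathway exports with planted overlap
#'
#' Each of `n_pathways` pathways draws a size from `pathway_size`, plants
#' `ceiling(overlap_fraction * size)` members from the corpus vocabulary
#' and fills the rest with pathway-exclusive symbols; edges form a star so
#' every member is recoverable from the edge list. Odd-numbered pathways
#' are TSV edge lists, even-numbered ones GMT membership sets. Continues
#' the stream started by [generate_corpus()]; the truth gains per-pathway
#' membership, the planted shared set and its per-compartment split.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [generate_corpus()].
#' @return List with `networks` (list of [pathway_network()]), `formats`
#'   (per-pathway `"tsv_edgelist"`/`"gmt"`) and updated `truth`.
#' @export
generate_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  dbs <- c("KEGG", "Reactome", "WikiPathways")
  networks <- list(); formats <- character(0)
  truth$pathways <- list()
  for (j in seq_len(cfg$n_pathways)) {
    s <- sample(seq(cfg$pathway_size[1], cfg$pathway_size[2]), 1L)
    k <- as.integer(ceiling(cfg$overlap_fraction * s))
    if (k > length(truth$vocabulary))
      stop("infeasible config: planted overlap exceeds vocabulary size",
           call. = FALSE)
    shared <- csort(sample(truth$vocabulary, k))
    novel <- if (s > k) sprintf("PW%02dX%03d", j, seq_len(s - k))
    else character(0)
    members <- c(shared, novel)
    acc <- sprintf("SYN-PW-%03d", j)
    db <- dbs[(j - 1L) %% 3L + 1L]
    fmt <- if (j %% 2L == 1L) "tsv_edgelist" else "gmt"
    nodes <- data.frame(symbol = members, entity_class = "protein",
                        xrefs = "", pathways = acc,
                        stringsAsFactors = FALSE)
    edges <- if (identical(fmt, "tsv_edgelist")) {
      hub <- members[1]
      data.frame(source = hub,
                 interaction = sample(c("activation", "inhibition",
                                        "binding"), s - 1L, replace = TRUE),
                 target = members[-1], stringsAsFactors = FALSE)
    } else .empty_pw_edges()
    net <- pathway_network(
      data.frame(source_db = db, accession = acc, stringsAsFactors = FALSE),
      nodes, edges)
    networks[[j]] <- net
    formats[j] <- fmt
    truth$pathways[[acc]] <- list(
      members = members, shared = shared, format = fmt,
      n_nodes = s, n_edges = nrow(edges),
      shared_by_compartment = lapply(
        structure(COMPARTMENTS, names = COMPARTMENTS), function(cmp)
          shared[vapply(truth$compartments[shared],
                        function(l) cmp %in% l, logical(1))]))
  }
  list(networks = networks, formats = formats, truth = truth)
}

#' Generate a synthetic GAF realizing the planted compartments
#'
#' Every vocabulary protein receives, for each of its planted compartment
#' labels, one GO cellular-component term drawn from the default
#' [compartment_mapping()] rows of that compartment — so classifying the
#' emitted GAF with the default mapping recovers the plant exactly.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list carrying `compartments`.
#' @return Character vector of GAF 2.2 lines (including the version
#'   header).
#' @export
generate_gaf <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  mapping <- compartment_mapping()
  rows <- character(0)
  for (sym in truth$vocabulary) {
    for (cmp in truth$compartments[[sym]]) {
      choices <- mapping$go_id[mapping$compartment == cmp]
      go <- choices[sample(length(choices), 1L)]
      rows <- c(rows, paste(
        "COAGKG", sprintf("SYN:%s", sym), sym, "located_in", go,
        "SYN:0000001", "IDA", "", "C", sym, "", "protein",
        "taxon:9606", "20220101", "COAGKG", "", "", sep = "\t"))
    }
  }
  c("!gaf-version: 2.2", rows)
}

#' Deterministic synthetic symbol map
#'
#' One UniProt-style accession per vocabulary symbol (plus identity HGNC
#' rows), for exercising [normalize_identifiers()].
#'
#' @param truth Truth list carrying `vocabulary`.
#' @return A `symbol_map` data frame.
#' @export
generate_symbol_map <- function(truth) {
  n <- length(truth$vocabulary)
  tab <- data.frame(
    namespace = c(rep("UNIPROT", n), rep("HGNC", n)),
    id = c(sprintf("P%05d", seq_len(n)), truth$vocabulary),
    symbol = rep(truth$vocabulary, 2), stringsAsFactors = FALSE)
  class(tab) <- c("symbol_map", "data.frame")
  tab
}

#' Write a pathway network as a harmonized export
#'
#' `write_pathway_tsv()` emits the TSV edge-list dialect [load_pathway()]
#' reads (`#pathway` identity comment, header row, one interaction per
#' row); `write_pathway_gmt()` emits one GMT line per pathway accession.
#'
#' @param net A [pathway_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_tsv <- function(net, path) {
  id <- net$pathway_ids[1, ]
  cls <- structure(net$nodes$entity_class, names = net$nodes$symbol)
  lines <- c(sprintf("#pathway\t%s\t%s", id$source_db, id$accession),
             "source\tsource_class\tinteraction\ttarget\ttarget_class",
             sprintf("%s\t%s\t%s\t%s\t%s", net$edges$source,
                     cls[net$edges$source], net$edges$interaction,
                     net$edges$target, cls[net$edges$target]))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_pathway_tsv
#' @export
write_pathway_gmt <- function(net, path) {
  lines <- vapply(seq_len(nrow(net$pathway_ids)), function(i) {
    acc <- net$pathway_ids$accession[i]
    members <- net$nodes$symbol[
      vapply(strsplit(net$nodes$pathways, ";"), function(v) acc %in% v,
             logical(1))]
    paste(c(acc, paste0(net$pathway_ids$source_db[i], " synthetic set"),
            members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Run the full synthetic-study generator
#'
#' Executes the three generator stages on one seeded stream (corpus, then
#' pathways, then GAF) and writes every artifact as plain text:
#' `corpus.bel`, `pathway_XX.tsv` / `pathway_XX.gmt`, `annotations.gaf`,
#' `symbol_map.tsv` and `truth.json`. Identical config + seed produce
#' byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return List with `documents`, `networks`, `gaf_lines`, `symbol_map`,
#'   `truth` and (when `dir` given) `paths`.
#' @export
simulate_study <- function(cfg, dir = NULL) {
  corpus <- generate_corpus(cfg)
  pw <- generate_pathways(cfg, corpus$truth)
  gaf_lines <- generate_gaf(cfg, pw$truth)
  smap <- generate_symbol_map(pw$truth)
  out <- list(documents = corpus$documents, networks = pw$networks,
              formats = pw$formats, gaf_lines = gaf_lines,
              symbol_map = smap, truth = pw$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(corpus = file.path(dir, "corpus.bel"))
    write_bel(corpus$documents[[1]], paths[["corpus"]])
    for (j in seq_along(pw$networks)) {
      ext <- if (pw$formats[j] == "gmt") "gmt" else "tsv"
      p <- file.path(dir, sprintf("pathway_%02d.%s", j, ext))
      if (ext == "gmt") write_pathway_gmt(pw$networks[[j]], p)
      else write_pathway_tsv(pw$networks[[j]], p)
      paths[sprintf("pathway_%02d", j)] <- p
    }
    paths["gaf"] <- file.path(dir, "annotations.gaf")
    writeLines(gaf_lines, paths[["gaf"]])
    paths["symbol_map"] <- file.path(dir, "symbol_map.tsv")
    utils::write.table(smap, paths[["symbol_map"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["truth"] <- file.path(dir, "truth.json")
    writeLines(jsonlite::toJSON(out$truth, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), paths[["truth"]])
    out$paths <- paths
  }
  out
}
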