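test_that("compile builds nodes, statement edges and induced edges", {
  empty <- kg_compile(list())
  s0 <- kg_stats(empty)
  expect_equal(s0$n_nodes, 0)
  expect_equal(s0$n_edges, 0)

  kg <- kg_compile(mini_doc())
  # leaves: heme, F8, VWF, platelet activation; composite: complex(heme,F8)
  expect_equal(kg_stats(kg)$n_nodes, 5)
  # 3 statement edges + 2 induced hasComponent edges
  expect_equal(kg_stats(kg, include_induced = TRUE)$n_edges, 5)
  expect_equal(kg_stats(kg, include_induced = FALSE)$n_edges, 3)
  expect_equal(sum(kg$edges$induced), 2)
  s <- kg_stats(kg)
  expect_equal(sum(s$n_by_type), s$n_nodes)
  expect_equal(s$n_proteins, 2)
  expect_equal(s$n_citations, 1)
})

test_that("compile is invariant under statement order", {
  cfg <- sim_config(n_proteins = 6, n_statements = 30, seed = 5)
  doc <- generate_corpus(cfg)$documents[[1]]
  shuf <- doc
  set.seed(1)
  shuf$statements <- doc$statements[sample(length(doc$statements))]
  g1 <- kg_compile(doc)
  g2 <- kg_compile(shuf)
  expect_identical(names(g1$terms), names(g2$terms))
  key <- function(g) sort(paste(g$edges$subject, g$edges$relation,
                                g$edges$object, g$edges$citation,
                                g$edges$evidence))
  expect_identical(key(g1), key(g2))
})

test_that("statements touching excluded formulations are skipped, counted", {
  doc <- parse_document(c(
    'a(TEXT:"heme arginate") -> p(HGNC:F3)',
    "a(TEXT:hemin) -> p(HGNC:F3)"))
  expect_message(kg <- kg_compile(doc), "1 statement")
  expect_equal(kg_stats(kg, include_induced = FALSE)$n_edges, 1)
  # the surviving statement was normalized to the canonical heme node
  expect_true("abundance(CHEBI:HEME)" %in% names(kg$terms))
})

test_that("merge obeys identity, idempotence and union laws", {
  g <- kg_compile(mini_doc())
  empty <- kg_compile(list())
  expect_identical(names(kg_merge(list(g, empty))$terms), names(g$terms))
  expect_equal(nrow(kg_merge(list(g, empty))$edges), nrow(g$edges))
  expect_equal(nrow(kg_merge(list(g, g))$edges), nrow(g$edges))

  other <- kg_compile(parse_document(c(
    'SET Citation = "22222222"',
    "a(CHEBI:heme) -> p(HGNC:F3)",
    "a(CHEBI:heme) -> p(HGNC:F8)")))
  m <- kg_merge(list(g, other))
  expect_setequal(names(m$terms), union(names(g$terms), names(other$terms)))
  expect_lte(nrow(m$edges), nrow(g$edges) + nrow(other$edges))
  # same triple, different citation: distinct evidence-level edges survive
  e <- m$edges[!m$edges$induced, ]
  heme_f8 <- e[e$subject == "abundance(CHEBI:HEME)" &
                 e$object == "protein(HGNC:F8)", ]
  expect_equal(nrow(heme_f8), 2)
})

test_that("merge rejects node-key collisions with differing types", {
  # node keys embed the term function, so a collision can only arise from
  # a corrupted or hand-edited graph; merge still guards against it
  g1 <- kg_compile(parse_document("a(TEXT:collagen) -> p(HGNC:F3)"),
                   normalize = FALSE)
  g2 <- g1
  g2$node_type[["abundance(TEXT:COLLAGEN)"]] <- "bioProcess"
  expect_error(kg_merge(list(g1, g2)), "node-type conflict")
})

test_that("stats recover planted protein counts exactly", {
  for (seed in c(3, 11)) {
    cfg <- sim_config(n_proteins = 14, n_statements = 50, seed = seed)
    sim <- generate_corpus(cfg)
    st <- kg_stats(kg_compile(sim$documents[[1]]), include_induced = FALSE)
    expect_equal(st$n_proteins, 14)
    expect_equal(st$n_edges, 50)
    expect_equal(sum(st$n_by_type), st$n_nodes)
  }
})

test_that("evidence_count counts incident statements, not induced edges", {
  kg <- kg_compile(mini_doc())
  # F8: appears in statement 1 (object), statement 2 via complex subject
  # and as act-object of statement 2
  expect_equal(evidence_count(kg, "protein(HGNC:F8)"), 2)
  expect_equal(evidence_count(kg, "abundance(CHEBI:HEME)"), 1)
  # the complex node: one statement edge; induced edges excluded
  ckey <- term_key(parse_term("complex(a(CHEBI:heme), p(HGNC:F8))"))
  expect_equal(evidence_count(kg, ckey), 1)
  expect_error(evidence_count(kg, "protein(HGNC:NOPE)"), "unknown")
  # invariant under merging with the empty graph
  m <- kg_merge(list(kg, kg_compile(list())))
  expect_equal(evidence_count(m, "protein(HGNC:F8)"), 2)
})

test_that("node-link JSON round-trips and GraphML export writes", {
  kg <- kg_compile(mini_doc())
  path <- tempfile(fileext = ".json")
  write_kg_json(kg, path)
  kg2 <- read_kg_json(path)
  expect_identical(names(kg2$terms), names(kg$terms))
  expect_equal(kg_edges(kg2), kg_edges(kg))
  # byte-stable across repeated writes
  p2 <- tempfile(fileext = ".json")
  write_kg_json(kg2, p2)
  expect_identical(readLines(path), readLines(p2))

  gml <- tempfile(fileext = ".graphml")
  write_kg_graphml(kg, gml)
  expect_true(file.size(gml) > 0)
  g <- kg_to_igraph(kg)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 5)
})
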