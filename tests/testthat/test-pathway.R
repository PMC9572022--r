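test_that("TSV edge lists load nodes, edges and pathway identity", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("#pathway\tReactome\tR-TEST-1",
               "source\tsource_class\tinteraction\ttarget\ttarget_class",
               "A\tprotein\tinteracts\tB\tprotein",
               "B\tprotein\tactivation\tC\tprotein"), p)
  net <- load_pathway(p)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$pathway_ids$accession, "R-TEST-1")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("source\tsource_class\tinteraction\ttarget\ttarget_class",
               "A\tprotein\tinteracts"), bad)
  expect_error(load_pathway(bad), "line 2")

  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_warning(net0 <- load_pathway(empty), "empty")
  expect_equal(nrow(net0$nodes), 0)
})

test_that("GMT lines load membership with empty edge sets", {
  p <- tempfile(fileext = ".gmt")
  writeLines("R-HSA-140834\textrinsic\tF3\tF7", p)
  net <- load_pathway(p)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 0)
  expect_setequal(net$nodes$symbol, c("F3", "F7"))
  expect_true(all(net$nodes$entity_class == "protein"))
  # lower-case members are named (non-gene) entities
  p2 <- tempfile(fileext = ".gmt")
  writeLines("WP272\tclotting\tF2\tfibrin", p2)
  net2 <- load_pathway(p2, source_db = "WikiPathways")
  expect_equal(net2$nodes$entity_class[net2$nodes$symbol == "fibrin"],
               "metabolite")
})

test_that("synthetic pathway exports round-trip with exact (n, m)", {
  cfg <- sim_config(n_proteins = 10, n_statements = 20, n_pathways = 4,
                    pathway_size = c(5, 9), seed = 21)
  sim <- simulate_study(cfg, d <- tempfile())
  for (j in seq_along(sim$networks)) {
    acc <- sim$networks[[j]]$pathway_ids$accession
    truth <- sim$truth$pathways[[acc]]
    ext <- if (sim$formats[j] == "gmt") "gmt" else "tsv"
    net <- load_pathway(file.path(d, sprintf("pathway_%02d.%s", j, ext)))
    expect_equal(nrow(net$nodes), truth$n_nodes)
    expect_equal(nrow(net$edges), truth$n_edges)
    expect_setequal(net$nodes$symbol, truth$members)
  }
})

test_that("identifier normalization maps, coalesces and rewires", {
  net <- pathway_network(
    data.frame(source_db = "Reactome", accession = "R-X",
               stringsAsFactors = FALSE),
    data.frame(symbol = c("P00451", "Q00001", "F9"),
               entity_class = "protein", xrefs = "", pathways = "R-X",
               stringsAsFactors = FALSE),
    data.frame(source = c("P00451", "Q00001"), interaction = "binding",
               target = c("F9", "F9"), stringsAsFactors = FALSE))
  map <- data.frame(namespace = "UNIPROT", id = c("P00451", "Q00001"),
                    symbol = c("F8", "F8"), stringsAsFactors = FALSE)
  class(map) <- c("symbol_map", "data.frame")
  out <- normalize_identifiers(net, map)
  # both accessions coalesce to F8; duplicate edges collapse; no self-loop
  expect_setequal(out$nodes$symbol, c("F8", "F9"))
  expect_equal(nrow(out$edges), 1)
  expect_false(any(out$edges$source == out$edges$target))
  # identity map leaves the network unchanged
  expect_equal(normalize_identifiers(net, NULL)$nodes, net$nodes)
  # unmapped foreign accessions are flagged, not silently kept
  out2 <- normalize_identifiers(
    net, within(map, symbol[2] <- "F8A")[1, , drop = FALSE])
  expect_true(any(startsWith(out2$nodes$symbol, "unmapped:")))
  expect_equal(attr(out2, "n_unmapped"), 1)
})

test_that("symbol maps reject duplicates and empty symbols", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("namespace\tid\tsymbol", "UNIPROT\tP00451\tF8",
               "UNIPROT\tP00451\tF9"), p)
  expect_error(read_symbol_map(p), "duplicate")
  writeLines(c("namespace\tid\tsymbol", "UNIPROT\tP00451\tF8"), p)
  expect_equal(read_symbol_map(p)$symbol, "F8")
})

test_that("combine is identity, additive on disjoint nets, order-invariant", {
  pm <- paper_mini()
  a <- pm$pathways$intrinsic
  b <- pm$pathways$extrinsic
  cc <- pm$pathways$common
  expect_equal(pw_combine(list(a))$nodes, a$nodes)
  # extrinsic and platelet sets are disjoint in the fixture
  d <- pw_combine(list(b, pm$pathways$platelet))
  expect_equal(nrow(d$nodes),
               nrow(b$nodes) + nrow(pm$pathways$platelet$nodes))
  # associativity / order invariance on node and edge sets
  abc1 <- pw_combine(list(a, b, cc))
  abc2 <- pw_combine(list(pw_combine(list(cc, b)), a))
  expect_equal(abc1$nodes[c("symbol", "entity_class", "pathways")],
               abc2$nodes[c("symbol", "entity_class", "pathways")])
  expect_equal(abc1$edges, abc2$edges)
  # shared proteins union, with per-pathway membership retained
  expect_lt(nrow(abc1$nodes),
            nrow(a$nodes) + nrow(b$nodes) + nrow(cc$nodes))
  f10 <- abc1$nodes[abc1$nodes$symbol == "F10", ]
  expect_setequal(strsplit(f10$pathways, ";")[[1]],
                  c("R-HSA-140834", "R-HSA-140837", "R-HSA-140875"))
})

test_that("combined synthetic pathways recover the planted union", {
  cfg <- sim_config(n_proteins = 12, n_statements = 20, n_pathways = 5,
                    pathway_size = c(4, 8), seed = 31)
  sim <- simulate_study(cfg)
  comb <- pw_combine(sim$networks)
  planted_union <- unique(unlist(lapply(sim$truth$pathways,
                                        `[[`, "members")))
  expect_equal(nrow(comb$nodes), length(planted_union))
  # every edge endpoint resolvable after combine
  expect_true(all(c(comb$edges$source, comb$edges$target) %in%
                    comb$nodes$symbol))
})
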