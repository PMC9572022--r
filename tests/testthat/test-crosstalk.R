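test_that("disjoint graph and pathway share nothing", {
  kg <- kg_compile(parse_document("a(CHEBI:heme) -> p(HGNC:TLR4)"))
  net <- pathway_network(
    data.frame(source_db = "KEGG", accession = "X",
               stringsAsFactors = FALSE),
    data.frame(symbol = c("F3", "F7"), entity_class = "protein",
               xrefs = "", pathways = "X", stringsAsFactors = FALSE),
    data.frame(source = "F3", interaction = "binding", target = "F7",
               stringsAsFactors = FALSE))
  r <- superimpose(kg, net, aliases = no_aliases)
  expect_length(r$common, 0)
  expect_setequal(r$pathway_only, c("F3", "F7"))
})

test_that("superimposition partitions the symbol union", {
  set.seed(7)
  pool <- sprintf("GENE%02d", 1:20)
  for (i in 1:50) {
    inst <- rand_overlap_instance(pool)
    r <- superimpose(inst$kg, inst$net, aliases = no_aliases)
    # brute-force oracle: the generating sets themselves
    expect_setequal(setdiff(r$common, "heme"),
                    intersect(inst$kg_prots, inst$net_prots))
    expect_true(length(intersect(r$common, r$kg_only)) == 0)
    expect_true(length(intersect(r$common, r$pathway_only)) == 0)
    expect_setequal(c(r$common, r$kg_only, r$pathway_only),
                    union(c(inst$kg_prots, "heme"), inst$net_prots))
  }
})

test_that("complex components and aliases make entities overlap-eligible", {
  kg <- kg_compile(parse_document(c(
    "complex(a(CHEBI:heme), p(HGNC:PROC)) =| act(p(HGNC:PROC))",
    'a(CHEBI:heme) -> a(TEXT:"thrombin")')))
  net <- pathway_network(
    data.frame(source_db = "Reactome", accession = "R-X",
               stringsAsFactors = FALSE),
    data.frame(symbol = c("PROC", "F2"), entity_class = "protein",
               xrefs = "", pathways = "R-X", stringsAsFactors = FALSE),
    data.frame(source = "PROC", interaction = "inhibition", target = "F2",
               stringsAsFactors = FALSE))
  r <- superimpose(kg, net)
  # PROC only appears inside the heme complex; thrombin matches F2 by alias
  expect_setequal(r$common, c("F2", "PROC"))
})

test_that("node sizes track evidence abundance with a floor of one", {
  pm <- paper_mini()
  r <- superimpose(pm$kg, pm$pathways$extrinsic)
  # F3 is curated in four statements
  expect_equal(unname(r$node_sizes[["F3"]]), 1 + 4)
  # pathway-only nodes carry no curated evidence: floor size
  expect_true(all(r$node_sizes[r$pathway_only] == 1))
  expect_true(all(r$node_sizes >= 1))
})

test_that("compartment restriction screens the protein overlap", {
  pm <- paper_mini()
  r_extra <- superimpose(pm$kg, pm$pathways$intrinsic, loc = pm$loc,
                         compartment = "extracellular")
  expect_setequal(r_extra$common,
                  c("F12", "F8", "F9", "KLKB1", "PROC", "VWF"))
  r_mem <- superimpose(pm$kg, pm$pathways$intrinsic, loc = pm$loc,
                       compartment = "membrane")
  expect_length(r_mem$common, 0)
  expect_error(superimpose(pm$kg, pm$pathways$intrinsic,
                           compartment = "membrane"),
               "localization")
})

test_that("hypergeometric overlap matches exact enumeration", {
  mk <- function(K, n, k, U) {
    r <- structure(list(counts = c(kg = K, pathway = n, common = k)),
                   class = "crosstalk_result")
    overlap_test(r, universe_size = U)
  }
  # zero overlap is never surprising
  expect_identical(mk(4, 3, 0, 10), 1)
  # all five drawn marked out of ten: 1 / C(10, 5)
  expect_equal(mk(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  # spot enumeration at moderate size
  expect_equal(mk(6, 4, 2, 11), enum_hyper_tail(2, 6, 4, 11),
               tolerance = 1e-12)
  # monotone: p non-increasing in the common count
  ps <- vapply(0:4, function(k) mk(5, 4, k, 12), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(mk(8, 4, 5, 10), "infeasible")
  expect_error(mk(8, 4, 1, 6), "infeasible")
})

test_that("gap reports list pathway-only targets with screening status", {
  pm <- paper_mini()
  cascade <- pw_combine(list(pm$pathways$intrinsic, pm$pathways$extrinsic,
                             pm$pathways$common))
  r <- superimpose(pm$kg, cascade)
  rep0 <- gap_report(r)
  expect_true(all(c("F10", "F11") %in% rep0$symbol))
  expect_true(all(rep0$literature_status == "not_screened"))
  # F10 sits in all three cascade parts and sorts first
  expect_equal(rep0$symbol[1], "F10")
  expect_equal(rep0$n_pathways[1], 3)
  expect_true(all(diff(rep0$n_pathways) <= 0))

  rep1 <- gap_report(r, pm$screened_path)
  expect_equal(
    rep1$literature_status[rep1$symbol == "F13A1"], "screened_negative")
  # screened-positive entries from other cell types are appended
  expect_true("PIK3CA" %in% rep1$symbol)

  # empty pathway-only set gives an empty report
  kg_all <- pm$kg
  r0 <- superimpose(kg_all, pm$pathways$extrinsic)
  r0$pathway_only <- character(0)
  expect_equal(nrow(gap_report(r0)), 0)
})

test_that("exports are complete and byte-deterministic", {
  pm <- paper_mini()
  r <- superimpose(pm$kg, pm$pathways$common, universe_size = 200)
  d1 <- tempfile(); d2 <- tempfile()
  export_report(r, d1, loc = pm$loc, screened = pm$screened_path)
  export_report(r, d2, loc = pm$loc, screened = pm$screened_path)
  for (f in c("overlap.tsv", "gaps.tsv", "overlay.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  tab <- read.delim(file.path(d1, "overlap.tsv"), stringsAsFactors = FALSE)
  expect_equal(nrow(tab),
               length(r$common) + length(r$kg_only) +
                 length(r$pathway_only))
  expect_setequal(unique(tab$class), c("common", "kg_only", "pathway_only"))
  # empty result: header-only TSV
  empty_r <- superimpose(kg_compile(list()), pathway_network())
  d3 <- tempfile()
  export_report(empty_r, d3)
  expect_equal(length(readLines(file.path(d3, "overlap.tsv"))), 1)
})
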