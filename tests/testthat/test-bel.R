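test_that("term parsing handles leaves, nesting, quoting and activity", {
  t1 <- parse_term("a(CHEBI:heme)")
  expect_equal(t1$fn, "abundance")
  expect_equal(t1$namespace, "CHEBI")
  expect_equal(t1$name, "heme")

  t2 <- parse_term('bp(GO:"blood coagulation")')
  expect_equal(t2$name, "blood coagulation")

  t3 <- parse_term("act(p(HGNC:PROC))")
  expect_true(t3$activity)
  expect_equal(t3$fn, "protein")

  t4 <- parse_term("complex(a(CHEBI:heme), complex(p(HGNC:F8), p(HGNC:VWF)))")
  expect_length(t4$components, 2)

  expect_error(parse_term("p(HGNC:F8"), "expected")
  expect_error(parse_term('p(HGNC:"")'), "empty")
  expect_error(parse_term("frob(HGNC:F8)"), "unknown BEL function")
})

test_that("canonical keys ignore component order, case and activity", {
  k1 <- term_key(parse_term("complex(p(HGNC:F8), p(HGNC:VWF))"))
  k2 <- term_key(parse_term("complex(p(HGNC:VWF), p(HGNC:F8))"))
  expect_identical(k1, k2)
  expect_identical(term_key(parse_term("p(HGNC:vwf)")),
                   term_key(parse_term("p(HGNC:VWF)")))
  expect_identical(term_key(parse_term("act(p(HGNC:F8))")),
                   term_key(parse_term("p(HGNC:F8)")))
  expect_false(term_key(parse_term("p(HGNC:F8)")) ==
                 term_key(parse_term("g(HGNC:F8)")))
})

test_that("random terms survive serialize/parse round trips", {
  set.seed(42)
  for (i in 1:300) {
    t <- rand_term()
    s <- serialize_term(t)
    t2 <- parse_term(s)
    expect_identical(serialize_term(t2), s)
    expect_identical(term_key(t2), term_key(t))
  }
})

test_that("heme synonyms canonicalize and formulations are excluded", {
  for (nm in c("hemin", "Hematin", "HEME"))
    expect_equal(normalize_entity(parse_term(sprintf("a(TEXT:%s)", nm))),
                 bel_term("abundance", "CHEBI", "heme"))
  expect_true(is_excluded(normalize_entity(
    parse_term('a(TEXT:"heme arginate")'))))
  expect_true(is_excluded(normalize_entity(
    parse_term('a(TEXT:"heme-albumin")'))))
  # identity on unrelated terms, and idempotence
  t <- parse_term("p(HGNC:F8)")
  expect_identical(normalize_entity(t), t)
  h <- normalize_entity(parse_term("a(TEXT:hemin)"))
  expect_identical(normalize_entity(h), h)
  # composites: component-wise, exclusion propagates
  expect_true(is_excluded(normalize_term(
    parse_term('complex(a(TEXT:"heme arginate"), p(HGNC:PROC))'))))
  c2 <- normalize_term(parse_term("complex(a(TEXT:hemin), p(HGNC:PROC))"))
  expect_identical(term_key(c2),
                   term_key(parse_term("complex(a(CHEBI:heme), p(HGNC:PROC))")))
})

test_that("documents bind annotation state to statements", {
  doc <- parse_document(c(
    'SET Citation = "12345"',
    'SET Setting = "in vitro"',
    'p(HGNC:F8) -| bp(GO:"blood coagulation")'))
  expect_length(doc$statements, 1)
  s <- doc$statements[[1]]
  expect_equal(s$relation, "decreases")
  expect_equal(s$annotations$setting, "in_vitro")
  expect_equal(s$citation, "12345")

  doc2 <- parse_document(
    "complex(a(CHEBI:heme), p(HGNC:PROC)) =| act(p(HGNC:PROC))")
  s2 <- doc2$statements[[1]]
  expect_equal(s2$relation, "directlyDecreases")
  expect_length(s2$subject$components, 2)
  expect_true(s2$object$activity)
})

test_that("dose and KD annotations parse with qualifiers and units", {
  doc <- parse_document(c(
    'SET Dose = "up to 100 µM"',
    'SET KD = "1.9 nM"',
    "a(CHEBI:heme) -> p(HGNC:F3)",
    'SET Dose = "3.2 µmol/kg"',
    "a(CHEBI:heme) -> p(HGNC:VWF)",
    'SET Dose = "a smidgen"',
    "a(CHEBI:heme) -> p(HGNC:F2)"))
  a1 <- doc$statements[[1]]$annotations
  expect_equal(a1$dose_value, 100)
  expect_equal(a1$dose_unit, "µM")
  expect_equal(a1$dose_qualifier, "up_to")
  expect_equal(a1$kd_value, 1.9)
  expect_equal(a1$kd_unit, "nM")
  a2 <- doc$statements[[2]]$annotations
  expect_equal(a2$dose_qualifier, "exact")
  expect_equal(a2$dose_unit, "µmol/kg")
  # unparseable dose text is preserved verbatim, not dropped
  a3 <- doc$statements[[3]]$annotations
  expect_true(is.na(a3$dose_value))
  expect_equal(a3$dose_text, "a smidgen")
})

test_that("parser accounts for every input line and reports errors", {
  lines <- c("# comment", "", 'SET Citation = "123"',
             "a(CHEBI:heme) -> p(HGNC:F8)",
             "p(HGNC:F8) ?? p(HGNC:VWF)",      # unknown relation
             "p(HGNC: -> p(HGNC:VWF)")          # malformed term
  expect_error(parse_document(lines, strict = TRUE), "line 5")
  doc <- parse_document(lines, strict = FALSE)
  expect_equal(unname(doc$line_counts["statements"]), 1)
  expect_equal(unname(doc$line_counts["errors"]), 2)
  expect_equal(sum(doc$line_counts), length(lines))
  expect_error(parse_document("p(HGNC:F8) binds p(HGNC:VWF)"),
               "unknown relation")
  expect_warning(parse_document(c('SET FavouriteColour = "red"',
                                  "a(CHEBI:heme) -> p(HGNC:F8)")),
                 "unknown annotation")
})

test_that("serialize/parse round-trips hold over generated corpora", {
  for (seed in c(1, 17, 99)) {
    cfg <- sim_config(n_proteins = 8, n_statements = 60, seed = seed)
    doc <- generate_corpus(cfg)$documents[[1]]
    reparsed <- parse_document(serialize_document(doc))
    expect_identical(doc_bytes(reparsed), doc_bytes(doc))
    expect_equal(length(reparsed$statements), length(doc$statements))
    # full field-level equality, including annotations
    expect_equal(reparsed$statements, doc$statements)
  }
  # empty document: header-only script
  empty <- generate_corpus(sim_config(n_proteins = 3, n_statements = 0))
  lines <- serialize_document(empty$documents[[1]])
  expect_true(any(grepl("^SET DOCUMENT", lines)))
  expect_length(parse_document(lines)$statements, 0)
})

test_that("serialization minimizes SET blocks and is byte-stable", {
  doc <- mini_doc()
  lines <- serialize_document(doc)
  # Citation set once (shared by all three), Evidence re-set per statement
  expect_equal(sum(grepl("^SET Citation", lines)), 1)
  expect_equal(sum(grepl("^SET Evidence", lines)), 3)
  expect_identical(serialize_document(doc), lines)
})
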