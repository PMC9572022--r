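# Shared generators and independent oracles for the test suite.

# random leaf / composite BEL terms, exercising quoting and nesting
rand_name <- function() {
  pool <- c("F8", "VWF", "heme", "blood coagulation", "factor VIII",
            "thromboxane A2", "GP6", "alpha-IIb_beta-3", "IL6",
            "platelet dense granule", "Thrombosis")
  sample(pool, 1)
}

rand_leaf <- function() {
  bel_term(sample(c("protein", "gene", "rna", "mirna", "abundance",
                    "bioProcess", "pathology"), 1),
           sample(c("HGNC", "CHEBI", "GO", "MESH", "TEXT"), 1),
           rand_name(),
           activity = runif(1) < 0.2)
}

rand_term <- function(depth = 0) {
  if (depth < 2 && runif(1) < 0.3) {
    n <- sample(2:3, 1)
    bel_term(sample(c("complex", "reaction"), 1),
             components = replicate(n, rand_term(depth + 1),
                                    simplify = FALSE))
  } else rand_leaf()
}

# canonical byte form of a document: statement-wise comparison proxy
doc_bytes <- function(doc) paste(serialize_document(doc), collapse = "\n")

# minimal hand-built document over the heme/F8/VWF fixture entities
mini_doc <- function() {
  parse_document(c(
    'SET Citation = "11111111"',
    'SET Evidence = "one"',
    "a(CHEBI:heme) -> p(HGNC:F8)",
    'SET Evidence = "two"',
    "complex(a(CHEBI:heme), p(HGNC:F8)) =| act(p(HGNC:F8))",
    'SET Evidence = "three"',
    'p(HGNC:VWF) -> bp(GO:"platelet activation")'))
}

# independent exhaustive hypergeometric tail: enumerate all n-subsets of a
# universe with K marked items and count those sharing >= k with the marks
enum_hyper_tail <- function(k, K, n, U) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(U, n)
  mean(colSums(subs <= K) >= k)
}

# random superimposition instance with brute-force expected partition:
# the generating sets ARE the oracle
rand_overlap_instance <- function(pool) {
  kg_prots <- sample(pool, sample(3:8, 1))
  net_prots <- sample(pool, sample(3:8, 1))
  lines <- c('SET Citation = "12345678"',
             sprintf("a(CHEBI:heme) -> p(HGNC:%s)", kg_prots))
  kg <- kg_compile(parse_document(lines))
  net <- pathway_network(
    data.frame(source_db = "KEGG", accession = "TEST",
               stringsAsFactors = FALSE),
    data.frame(symbol = net_prots, entity_class = "protein",
               xrefs = "", pathways = "TEST", stringsAsFactors = FALSE),
    data.frame(source = net_prots[1], interaction = "binding",
               target = net_prots[-1], stringsAsFactors = FALSE))
  list(kg = kg, net = net, kg_prots = kg_prots, net_prots = net_prots)
}

# neutral alias set: tests that do not exercise alias resolution use this
# so overlap is purely symbol-based
no_aliases <- structure(character(0), names = character(0))
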