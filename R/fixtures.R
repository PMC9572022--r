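#' The bundled "paper-mini" study fixture
#'
#' A compact, fully in-repo study: a hand-curated BEL corpus of heme
#' effects on coagulation factors and platelet signaling (with dose,
#' route, cell-type and K_D context), synthetic stand-ins for the
#' Reactome fibrin-clot-formation pathway exports (intrinsic
#' R-HSA-140837, extrinsic R-HSA-140834, common R-HSA-140875), a
#' synthetic KEGG platelet-activation gene set (HSA04611), a synthetic
#' GAF with compartment annotations, and a curated literature-screening
#' status table. Everything needed to run the full crosstalk analysis
#' without downloads.
#'
#' @return A list: `kg` (compiled `coag_kg`), `doc` (the parsed
#'   `bel_document`), `pathways` (named list of [pathway_network()]:
#'   `intrinsic`, `extrinsic`, `common`, `platelet`), `loc`
#'   (`localization_table` over all fixture proteins), and
#'   `screened_path` (TSV path for [gap_report()]).
#' @examples
#' pm <- paper_mini()
#' superimpose(pm$kg, pm$pathways$extrinsic)$common
#' @export
paper_mini <- function() {
  ext <- function(...) system.file("extdata", ..., package = "coagkg")
  doc <- read_bel(ext("paper_mini.bel"))
  kg <- kg_compile(doc)
  pathways <- list(
    intrinsic = load_pathway(ext("pathways",
                                 "reactome_intrinsic_synthetic.tsv"),
                             source_db = "Reactome"),
    extrinsic = load_pathway(ext("pathways",
                                 "reactome_extrinsic_synthetic.tsv"),
                             source_db = "Reactome"),
    common = load_pathway(ext("pathways", "reactome_common_synthetic.tsv"),
                          source_db = "Reactome"),
    platelet = load_pathway(ext("pathways", "kegg_platelet_synthetic.gmt"),
                            source_db = "KEGG"))
  gaf <- read_gaf(ext("paper_mini_synthetic.gaf"))
  symbols <- union(unique(gaf$symbol),
                   .kg_symbols(kg, entity_aliases())$proteins)
  loc <- build_localization(symbols, gaf)
  list(kg = kg, doc = doc, pathways = pathways, loc = loc,
       screened_path = ext("screened_status_synthetic.tsv"))
}
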