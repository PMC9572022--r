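---
title: "Knowledge-graph crosstalk analysis of heme and blood coagulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph crosstalk analysis of heme and blood coagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagkg)
```

## Scientific background

Intravascular hemolysis floods plasma with free heme. Beyond the
scavenging capacity of haptoglobin, albumin and hemopexin, the labile
heme pool binds and functionally modulates proteins of both arms of
hemostasis: the enzymatic clotting cascade (intrinsic / extrinsic /
common pathway) and platelet adhesion–activation signaling. The
evidence — binding affinities, dose–response observations, cell-type and
route-specific effects, clinical symptoms of therapeutic heme
injection — is heterogeneous and partially contradictory, and many
cascade members have never been tested against heme at all.

`coagkg` treats this body of evidence as a *knowledge graph* and asks a
structural question: where does the curated heme-effect network touch
the canonical pathway networks of blood coagulation, and where are the
gaps?

## The curation model

### Statements

A curated assertion is a triple `subject relation object` over typed,
namespaced entities. The term grammar covers nine functions (protein,
gene, RNA, miRNA, chemical abundance, complex, biological process,
pathology, reaction) and an `act()` molecular-activity modifier. The
relation vocabulary is closed to six members (`increases`,
`directlyIncreases`, `decreases`, `directlyDecreases`, `association`,
`regulates`); physical binding is expressed as complex formation
(`complex(a(CHEBI:heme), p(HGNC:PROC))` as subject or object), following
BEL convention, so no separate `binds` relation exists. Nested
statements (an object that is itself a statement) are rejected with a
clear error: the curated content in scope does not need them, and
refusing them keeps graph compilation unambiguous.

### Context annotations

Each statement carries the experimental context the observation was made
in: cell type, species, setting (`in_vitro` / `in_vivo` / `ex_vivo`),
heme dose, administration route, and, for binding statements, the
equilibrium dissociation constant K~D~. Doses parse into (qualifier,
value, unit): `"up to 100 µM"` becomes (`up_to`, 100, µM); dose units
are restricted to µM, mM, nmol, µmol/kg and mg/kg, K~D~ units to nM and
µM. A dose string that does not parse is *kept verbatim* and flagged
rather than dropped — context is provenance, and silently discarding it
would bias any later dose-stratified analysis.

### Entity normalization

Three free-text names of the same chemical species — heme, hemin
(Fe(III) chloride salt) and hematin (Fe(III) hydroxide) — canonicalize,
case-insensitively, to the single node `a(CHEBI:heme)`. Pharmaceutical
heme formulations (heme arginate, heme–albumin) are excluded outright:
they were engineered to *avoid* labile-heme effects, so statements about
them would contaminate the labile-heme network. Both lists ship as an
editable TSV (`inst/extdata/heme_synonyms.tsv`). Normalization is
idempotent, and exclusion propagates from a component to the whole
complex.

### Node identity

The canonical key of a term is a deterministic function of (function,
namespace, upper-cased name, sorted component keys). Consequences:
component order in a complex never matters, name case never matters, and
the `act()` modifier is *not* part of identity — an activity is an
aspect of a node, not a different node. `TEXT`-namespace entities unify
with database-namespaced ones only through normalization (heme) or the
alias table (below); we deliberately do not fold `TEXT:F8` into
`HGNC:F8` by name alone, because free-text names are not guaranteed to
be gene symbols.

## Graph compilation and merging

`kg_compile()` produces one node per distinct canonical key and one edge
per statement. Two statements asserting the same triple from different
publications remain two edges: the graph is a **multigraph whose edge total is
an evidence count**, which is also what makes node sizing by "abundance
in the underlying relations" meaningful. Complex and reaction nodes
additionally induce `hasComponent` edges to their components; induced
edges are tagged and excluded from evidence counting, and `kg_stats()`
takes an `include_induced` flag (default `TRUE`) because both
conventions occur in deposited graphs.

`kg_merge()` unions node sets by canonical key and deduplicates edges on
the full evidence-level key (subject, relation, object, citation,
evidence). This makes merge idempotent and merge-with-empty the
identity — properties the test suite asserts — and it means merging a
focused corpus into a larger one can only add knowledge, never inflate
evidence counts.

Compilation sorts nodes by key (locale-independent C ordering,
`method = "radix"`), so the result is invariant under statement order
and exports are byte-stable across systems.

## Pathway ingestion

Pathway databases are consumed as *harmonized flat exports*: a TSV edge
list (`source, source_class, interaction, target, target_class`, with a
`#pathway` identity comment) or a standard GMT membership line (nodes
only). Direct KGML/GPML/BioPAX parsing is out of scope by design: the
exchange format decouples the analysis from database release schemas,
and the original analysis likewise consumed pre-harmonized output.
Non-protein pathway members (fibrin, collagen, small molecules such as
thromboxane A2) are retained with class `metabolite`/`process` because
they legitimately appear as common nodes; in GMT lines, where no class
column exists, lower-case members are taken as named non-gene entities.
Interaction types are free strings and never participate in overlap
identity. `normalize_identifiers()` maps foreign protein identifiers to
HGNC symbols, coalescing nodes that map to one symbol (self-loops
created purely by coalescence are dropped; pre-existing loops are kept)
and flagging unmapped UniProt-style accessions with an `unmapped:`
prefix rather than mistaking them for symbols.

## Subcellular stratification

The compartment screen classifies proteins as extracellular, membrane
and/or intracellular from GO cellular-component annotations (GAF 2.2;
aspect C rows, `NOT` qualifiers excluded, evidence codes retained with
an optional filter). The default mapping is a small flat table of nine
high-level CC terms (extracellular region/space; membrane, plasma
membrane, external side of plasma membrane; intracellular, cytoplasm,
cytosol, nucleus).

Classification is **multi-label with no precedence**: a receptor
annotated to both the plasma membrane and the cytosol is counted in both
compartments. We adopt multi-label because per-compartment totals of a
curated protein set can legitimately exceed the number of proteins
(e.g. 22 + 10 + 18 = 50 labels over 47 proteins), which is exactly what
secreted-and-stored proteins such as VWF produce; a forced single label
would hide one of the two biologically real pools.

An optional mode propagates labels through the is_a/part_of ancestor
closure of an OBO file (`read_obo_ancestors()`). It is **off by
default**: the flat mapping gives identical results regardless of which
ontology release a user has, and reproducibility across releases matters
more here than recall. Compartment counts derived from any live GO
snapshot are version-sensitive and should be treated as soft numbers.

## Superimposition and the overlap statistic

`superimpose()` intersects two symbol sets:

* **KG side** — protein nodes by upper-cased HGNC symbol, *including
  proteins that only occur as complex components* (a heme-bound factor
  is an overlap-eligible factor); abundance/process/pathology nodes by
  case-folded name.
* **Pathway side** — protein nodes by symbol; named entities by
  case-folded name.

A curated alias table (`inst/extdata/entity_aliases.tsv`) resolves the
literature's trivial names to symbols before matching (thrombin = F2,
tissue factor = F3, APC = PROC, GPVI = GP6, ...), because curated text
and database exports mix the two vocabularies freely. With a
localization table and a compartment, the protein sets on both sides are
restricted to that compartment first; named entities are not restricted
(they carry no GO annotation).

The result partitions the symbol union into `common`, `kg_only` and
`pathway_only`; the partition property (pairwise disjoint, covering) and
equality with brute-force set intersection over 1000 random instances
are asserted in the test suite. Node sizes are `1 + evidence count`
(statement edges incident to any node representing the symbol), floor 1
for pathway-only nodes — proportional to how heavily studied each entity
is.

The overlap statistic is the exact upper-tail hypergeometric probability
`P(X >= |common|)` of drawing the pathway's protein set from a universe
containing the KG's proteins as marked items, computed with
`stats::phyper` and cross-checked in the tests against exhaustive subset
enumeration (agreement to 1e-12 for every universe up to 12). The
statistic is an explicit addition of this package: the overlap analysis
it accompanies reports membership, not significance, and the universe
size is a user choice (we default to reporting no probability unless a
universe is given, since "all human proteins" and "all cascade proteins"
give very different baselines).

`gap_report()` turns pathway-only symbols into a ranked target list
(pathway count descending), optionally annotated with a curated
literature-screening status. The screening layer is an *input* — the
product of manual literature review — never computed.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure the analysis
assumes, with planted ground truth at every stage:

* a heme-centric corpus: heme is the hub in a configurable fraction of
  statements (default 0.70), as a plain subject or a heme–protein
  complex (`p_complex`, default 0.15), cycling through the vocabulary so
  the planted protein count is exact;
* pathway exports sharing `ceiling(overlap_fraction × size)` proteins
  with the corpus (recorded per compartment), half TSV, half GMT;
* a GAF realizing each protein's planted compartment labels through the
  default mapping.

Defaults mirror the curated corpus scale — 47 proteins, 426 statements,
6 pathways, compartment weights (0.44, 0.20, 0.36) reproducing the
22/10/18 extracellular/membrane/intracellular split in expectation, and
a multilabel probability of 0.06 (≈3 dual-labelled proteins among 47).
The vocabulary is coagulation-flavored (F2, F3, F8, VWF, PROC, KLKB1,
GP6, SYK, ...) before falling back to synthetic symbols, so fixtures
read like real curation.

One seeded stream drives a run, consumed in documented order (corpus,
then compartment labels, then pathways, then GAF), so identical
config + seed give byte-identical artifacts, and adding a later stage
never perturbs earlier outputs.

What the generator does **not** emulate: citation structure of real
literature (evidence sentences are synthetic), kinetic or dynamical
realism of doses and affinities, correlation between a protein's
compartment and its pathway membership, and curation noise (typos,
dialect drift). Passing planted-recovery tests therefore demonstrates
the pipeline's bookkeeping is exact, not that real curated corpora are
error-free; the strict/lenient parser switch exists precisely because
external deposits may differ cosmetically from this dialect.

## The bundled "paper-mini" study

`paper_mini()` loads a compact hand-curated corpus (22 proteins, 49
edges): heme binding to FVIII(a), APC, GPVI and fibrinogen with their
K~D~ values, tissue-factor induction across cell types and routes, the
VWF axis, contact-system activation, and the platelet signaling cascade.
Two published K~D~ readings for FVIII/FVIIIa exist with swapped values
(1.9 vs 12.7 nM); the corpus stores **both** as separate statements with
a `Note` annotation naming the reading, rather than silently choosing.
The accompanying pathway files are *synthetic stand-ins* (marked in
their filenames) for the Reactome cascade exports and a KEGG platelet
set: membership is hand-assembled to be biologically plausible, not a
redistribution of database content. On this fixture the three cascade
overlays return exactly the expected common-node sets (intrinsic:
KLKB1, F8, F9, F12, PROC, VWF; extrinsic: F3; common pathway: F2, F5,
F8, PROC, fibrin, fibrinogen).

```{r fixture}
pm <- paper_mini()
superimpose(pm$kg, pm$pathways$intrinsic)$common
```

## Numerical and design choices

* **Determinism** — all symbol and key ordering uses C-locale radix
  sorting; exports (node-link JSON, TSV, GraphML via `igraph`) are
  byte-stable across repeated writes.
* **Degenerate inputs** — empty documents serialize to header-only
  scripts; empty graphs and empty pathway files are legal everywhere;
  zero overlap gives an overlap probability of exactly 1; infeasible
  hypergeometric counts error rather than returning nonsense.
* **Edge dedup key** — includes citation *and* evidence text, so two
  observations from one publication remain distinct edges; this is the most
  conservative reading of evidence-level counting.
* **Line accounting** — the parser never silently drops a line:
  statements + errors + blank/comment/directive lines always sum to the
  input length (asserted in the tests).
* **Problem sizes in tests** — oracle suites run at sizes where
  exhaustive enumeration is exact (universes ≤ 12 for the
  hypergeometric check; 1000 random superimposition instances; 50
  replicate synthetic studies for pipeline recovery), chosen so the full
  suite completes in about a minute on one core.

## Limitations

* The parser covers the curation subset only: no protein modifications,
  fusions, translocations or nested statements from the full BEL 2.x
  specification.
* Compartment classification is only as good as the supplied GAF and
  flat mapping; with live GO snapshots the counts are release-sensitive.
* The hypergeometric test treats proteins as exchangeable; it ignores
  study bias (heavily studied proteins are more likely to be curated
  *and* to be pathway members), so its p-value is a descriptive
  calibration, not a causal claim.
* Pathway exports are snapshots; combined-network sizes depend on the
  database release and are not meaningful to compare bit-for-bit.
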