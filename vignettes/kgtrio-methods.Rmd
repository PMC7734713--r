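---
title: "Mining gene-disorder-drug relationships across biomedical RDF datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene-disorder-drug relationships across biomedical RDF datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgtrio)
```

## The problem

Assertions about genes, disorders and drugs are scattered over heterogeneous
biomedical datasets — literature-derived predication stores, pathway
databases, protein databases, pharmacogenomics resources — each published as
RDF under its own URI namespace, with the same real-world entity appearing
under different local names ("PARK2" here, "park2_pg" there). A question
such as *which drugs treat this disorder?* can rarely be answered from one
source alone; the answer is the union of what all sources assert about the
same underlying concepts.

kgtrio integrates such datasets into one provenance-aware triple store,
aligns entities and predicates at the concept level, and answers the nine
directed query patterns that cover every ordered pair of the three entity
classes, reporting for each result which datasets support it.

## The integration procedure

Integration runs in a fixed sequence (`integrate_datasets()`):

1. **Load and merge.** Each dataset (N-Triples or Turtle) is parsed into
   triples tagged with its dataset id. Exact duplicates within one source
   collapse; the same statement from two sources is kept once per source,
   because downstream evaluation counts results per dataset.
2. **Index.** A compound predicate–subject–object index backs all later
   lookups, so traversals never scan the full store.
3. **Concept annotation.** Every subject, predicate and object is reduced to
   its URI local name, normalized (case-folded, `_`/`-` to spaces,
   whitespace collapsed) and looked up in a flat-file concept lexicon that
   maps surface forms to concept unique identifiers (CUIs). The lexicon
   plays the role a metathesaurus plays for real vocabularies: synonymous
   forms share a CUI. Matching is exact after normalization — no stemming,
   no fuzzy matching — so a miss yields `NA` rather than a guess.
4. **Predicate extension.** All predicates observed in the merged store are
   grouped into alias sets by shared CUI (`extend_predicates()`), widening
   predicate matching across vocabularies (e.g. a `TREATS` and a
   `treated_by` predicate naming the same concept).
5. **Link mining.** Two triples link when their subject CUIs, predicate
   CUIs (directly or via alias groups) and object CUIs agree while the
   namespace of the subject or the object differs — the same conceptual
   statement written by two sources under different names
   (`mine_links()`). Triples with any unresolved CUI never link.
   Enumeration is per CUI signature bucket through the index, never over
   all triple pairs.
6. **Materialization.** Each link adds up to three bridge triples under a
   reserved source id: `sameConcept` assertions between the paired subjects
   and between the paired objects, plus one cross-namespace assertion
   (left subject, left predicate, right object). This is the minimum that
   lets a one-hop query starting in one namespace reach entities known only
   to another dataset. Re-materializing is a no-op.

The linking condition requires a namespace difference on the subject *or*
object, exactly; a predicate-namespace difference alone does not create a
link, since two vocabularies naming the same relation between the same
entity URIs add no cross-dataset information.

## Relation typing and the nine query patterns

Entities are classed as gene, drug or disorder from three sources of
evidence in priority order: an explicit `rdf:type` to the reserved
`myclass:` vocabulary, else the lexicon's per-CUI class, else an optional
class-map file. Conflicting `rdf:type` assertions are an error; lower
priority evidence is silently overridden. Real datasets are incompletely
typed, so triples with an unclassified endpoint are counted and reported,
not failed on.

`classify_relations()` partitions predicate occurrences into nine *directed*
relation sets keyed by (subject class, object class). Direction matters —
the predicates serving "disorders caused by a gene" differ from those
serving "genes causing a disorder" — so inverse sets are never auto-filled.
The sets may overlap freely: a generic association predicate legitimately
occurs between every class pair.

A query (`run_pattern()`) follows the one-hop procedure: resolve the seed
label through the reserved label predicate to its URI set (exact,
case-insensitive match; all namespaces); traverse every predicate of the
relation set keyed by the pattern's (seed class, target class); drop
objects that are not of the target class; deduplicate hits at the concept
level (CUI when resolvable, else URI); attach supporting source datasets
and predicates. The seed concept is excluded from its own results unless a
triple asserts it reflexively (subject equal to object). Output order is by
label then URI, so identical inputs give identical reports. Multi-hop
traversal is deliberately out of scope for the core procedure; every hit is
exactly one predicate away from a seed URI, which keeps results explainable
by their `via_predicates`.

The package ships a reference vocabulary of 25 predicates (R1–R25) over
four source prefixes and the nine predicate relationship groups (PRG1–PRG9)
that serve the patterns Q1–Q9 (`packaged_vocabulary()`). Three vocabulary
entries — `kegg:hasDisease`, `kegg:hasDrug` and `pharmgkb:Related_Drugs` —
belong to no group; the vocabulary carries name-derived endpoint classes
for them (gene→disorder, disorder→drug, drug→drug) so that generators and
compatibility checks can still place them. The group tables are reference
data for query configuration; on data, relation sets are always derived
from the store itself.

## Evaluation arithmetic

Expert evaluation of query results is summarised as per-query, per-source
cells of (correct results : total results). `precision_table()` derives row,
column and grand totals with precision `100 * correct / total`, rounded
half-up at two decimals using exact integer arithmetic
(`floor((20000c + t) / 2t) / 100`), so printed table values never drift
through floating point. Precision of an empty cell is undefined (`NA`),
never zero. Relative improvement between two precisions is computed **on
the two-decimal rounded values** with the old value as denominator —
`relative_improvement(87.68, 89.88)` is `2.51` — because that is the
arithmetic under which the packaged tables' improvement figures are
self-consistent; unrounded inputs would give 2.50. The packaged count
fixtures (`packaged_counts()`) cover a baseline fusion method and the
integrated method; `count_deltas()` reports raw count differences only,
leaving the denominator choice to the caller, as the two natural relative
readings disagree.

## What the synthetic generator emulates

`generate_toy_kg()` builds a four-source toy corpus in which every module is
testable without downloads:

* one entity population (default 20 genes, 10 drugs, 10 disorders — desk
  scale, chosen so that class pools are large enough for hundreds of
  distinct assertions yet brute-force oracles stay instant) shared by all
  sources under source-specific surface decorations (case changes and
  suffixes only, each variant carried by the generated lexicon, so concept
  resolution is exact by construction and link mining is isolated from
  fuzzy-matching concerns, which are a non-goal);
* assertions drawn from the packaged 25-predicate vocabulary restricted to
  class-compatible endpoints, with `rdf:type` and label triples for every
  referenced entity. Predicates are consumed in reshuffled cycles of the
  full vocabulary rather than iid draws, so any run of at least 25
  assertions per source covers every predicate — iid sampling would miss
  some predicate with non-negligible probability at any fixed size;
* cross-dataset duplications, each planted with probability `p_dup`
  (default 0.3, a moderate overlap; acceptance checks also exercise 0 and
  1) and recorded as ground-truth links.

Distinct assertions are kept concept-wise unique across sources via a
global signature registry, so the planted links are *exactly* the links a
correct miner should find — recall below 1 or any spurious link is a bug,
not noise. Sources are generated sequentially from per-source seeds derived
from the master seed; the order is fixed, so the first sources' content
does not change if another source is appended. Identical configurations
produce byte-identical files.

What the generator does **not** emulate: literature-extraction noise,
incomplete typing, polysemous surface forms, or realistic degree
distributions. Passing tests therefore demonstrate correctness of the
integration and query logic under exact concept resolution, not robustness
to dirty real-world vocabularies — on real data, entities missing from the
lexicon simply never link, failing safe.

The brute-force oracles (`oracle_links()`, all-pairs evaluation of the
linking condition; `oracle_query()`, full linear-scan resolve–traverse–
filter) share no traversal code with the engine and are intended for stores
of at most a few thousand triples.

## Numerical and degenerate-input choices

* Namespace splitting is at the last `#`, else the last `/`; a string with
  neither is all local name. Literals have an empty namespace, so two
  literal objects never differ in namespace.
* Literal objects participate in linking only if their lexical form
  resolves to a CUI.
* Polysemy in a lexicon file (one normalized term, two CUIs) is rejected at
  load rather than silently resolved.
* Empty inputs degrade to empty outputs everywhere (empty store, empty
  lexicon, zero-count generator configs, empty link sets), never to errors.
* Unordered link pairs are stored in a canonical orientation
  (lexicographically smaller triple first) so set comparisons and file
  outputs are deterministic.

## Command-line interface and problem sizes

`exec/kgtrio` exposes `simulate`, `integrate`, `classify`, `query` and
`evaluate`; all outputs are written atomically (temp file and rename) and
no subcommand mutates its inputs. One limitation: a merged store written as
plain N-Triples loses per-dataset provenance (quad/named-graph semantics
are out of scope), so per-source counts in CLI query reports collapse to
one source; the in-memory pipeline retains full provenance.

The packaged checks run the engine-versus-oracle comparison on 100 seeded
graphs of roughly 250–300 triples each and planted-recovery on 20 fully
duplicated graphs — sizes at which the quadratic oracle is exact yet the
whole suite completes in about a minute on one CPU.
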