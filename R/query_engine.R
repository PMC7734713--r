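#' Resolve an entity label to URIs
#'
#' Finds every subject asserted to carry the given label through the
#' reserved `myprop:Label` predicate, across all sources. Matching is exact
#' after [normalize_term()] on both sides (case-insensitive, punctuation
#' variants of spacing collapse); no substring or fuzzy matching.
#'
#' @param store a `TripleStore`
#' @param label entity label as entered by the user
#' @return character vector of URIs (empty when nothing matches)
#' @export
resolve_label <- function(store, label) {
  dt <- lookup_triples(store, predicate = kg_label_predicate())
  dt <- dt[dt$literal]
  if (!nrow(dt)) return(character())
  hit <- normalize_term(dt$object) == normalize_term(label)
  sort(unique(dt$subject[hit]))
}

#' Run one of the nine query patterns
#'
#' Implements the one-hop traversal: resolve the seed label to its URI set
#' S; for every s in S and every predicate p in the relation set keyed by
#' (seed class, target class), collect the objects of (s, p, .) triples;
#' drop collected entities that are not of the target class; deduplicate at
#' the concept level (by CUI when the entity resolves in the lexicon, else
#' by URI) and attach the supporting source datasets and predicates. The
#' seed concept itself is excluded from the results unless an explicitly
#' reflexive triple (subject equal to object) asserts it. Output order is
#' deterministic: by label, then URI.
#'
#' @param store a `TripleStore`
#' @param relsets a `RelationSets` from [classify_relations()]
#' @param pattern_id one of `"Q1"`..`"Q9"`
#' @param seed_label entity label to start from
#' @param classes optional entity-class map; computed from the store's
#'   `rdf:type` triples (plus lexicon) when omitted
#' @param lexicon optional `ConceptLexicon` used for concept-level
#'   deduplication; URI-level dedup when omitted
#' @return an object of class `QueryResult`: list with fields `pattern`
#'   (row of [query_patterns()]), `seed_label`, `seed_uris`, `seed_found`,
#'   and `hits` (data.table with columns `concept_key`, `uri` (first URI seen),
#'   `label`, `sources` and `via_predicates` list-columns)
#' @export
run_pattern <- function(store, relsets, pattern_id, seed_label,
                        classes = NULL, lexicon = NULL) {
  pats <- query_patterns()
  if (!pattern_id %in% pats$id) {
    stop(sprintf("invalid query pattern id: %s (expected Q1..Q9)", pattern_id), call. = FALSE)
  }
  pat <- pats[pats$id == pattern_id]
  if (is.null(classes)) classes <- assign_classes(store, lexicon)
  seeds <- resolve_label(store, seed_label)
  result <- structure(list(pattern = pat, seed_label = seed_label,
                           seed_uris = seeds, seed_found = length(seeds) > 0L,
                           hits = empty_hits()), class = "QueryResult")
  if (!length(seeds)) return(result)
  preds <- relsets[[pat$relation_key]]
  if (!length(preds)) return(result)
  temp <- lookup_triples(store, predicate = preds, subject = NULL)
  temp <- temp[temp$subject %in% seeds & !temp$literal]
  if (!nrow(temp)) return(result)
  # class filter: keep only objects of the target class
  ocls <- unname(classes[temp$object])
  temp <- temp[!is.na(ocls) & ocls == pat$target_class]
  if (!nrow(temp)) return(result)

  key_of <- function(uris) {
    if (is.null(lexicon)) return(uris)
    k <- cui_of(lexicon, uris)
    ifelse(is.na(k), uris, k)
  }
  temp[, concept_key := key_of(object)]
  seed_keys <- unique(key_of(seeds))
  # exclude the seed concept unless asserted reflexively
  reflexive <- unique(temp$concept_key[temp$subject == temp$object])
  temp <- temp[!(temp$concept_key %in% setdiff(seed_keys, reflexive))]
  if (!nrow(temp)) return(result)

  labels <- label_map(store)
  hits <- temp[, list(
    uri = sort(object)[1L],
    label = {
      ls <- unname(labels[sort(unique(object))])
      ls <- ls[!is.na(ls)]
      if (length(ls)) ls[1L] else local_name(sort(object)[1L])
    },
    sources = list(sort(unique(source))),
    via_predicates = list(sort(unique(predicate)))
  ), by = "concept_key"]
  data.table::setorderv(hits, c("label", "uri"))
  result$hits <- hits
  result
}

empty_hits <- function() {
  data.table::data.table(concept_key = character(), uri = character(), label = character(),
                         sources = list(), via_predicates = list())
}

# label lookup: URI -> first label literal (alphabetical for determinism)
label_map <- function(store) {
  dt <- lookup_triples(store, predicate = kg_label_predicate())
  dt <- dt[dt$literal]
  if (!nrow(dt)) return(stats::setNames(character(), character()))
  dt <- dt[order(dt$subject, dt$object)]
  dt <- dt[!duplicated(dt$subject)]
  stats::setNames(dt$object, dt$subject)
}

#' @export
print.QueryResult <- function(x, ...) {
  cat(sprintf("<QueryResult %s (%s -> %s): seed '%s' (%d URI(s)), %d hit(s)>\n",
              x$pattern$id, x$pattern$seed_class, x$pattern$target_class,
              x$seed_label, length(x$seed_uris), nrow(x$hits)))
  if (nrow(x$hits)) {
    for (i in seq_len(nrow(x$hits))) {
      cat(sprintf("  %-20s [%s]\n", x$hits$label[i],
                  paste(x$hits$sources[[i]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Per-source provenance counts of a query result
#'
#' A hit contributes one count to every dataset that asserted at least one
#' supporting triple for it; `total` is the number of distinct hits, which
#' can be smaller than the sum of the per-source counts when hits are
#' multiply sourced.
#'
#' @param result a `QueryResult`
#' @return list with `by_source` (named integer vector) and `total`
#' @export
provenance_counts <- function(result) {
  srcs <- unlist(result$hits$sources)
  by_source <- if (length(srcs)) {
    tab <- table(srcs)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  list(by_source = by_source, total = nrow(result$hits))
}

#' Serialize a query result as JSON
#' @param result a `QueryResult`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_query_result <- function(result, path) {
  counts <- provenance_counts(result)
  obj <- list(
    schema_version = 1L,
    pattern = result$pattern$id,
    seed_class = result$pattern$seed_class,
    target_class = result$pattern$target_class,
    seed_label = result$seed_label,
    seed_found = result$seed_found,
    seed_uris = as.list(result$seed_uris),
    hits = lapply(seq_len(nrow(result$hits)), function(i) list(
      key = result$hits$concept_key[i],
      uri = result$hits$uri[i],
      label = result$hits$label[i],
      sources = as.list(result$hits$sources[[i]]),
      via_predicates = as.list(result$hits$via_predicates[[i]])
    )),
    counts_by_source = as.list(counts$by_source),
    total = counts$total
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
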