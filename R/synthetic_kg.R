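SYNTH_SOURCES <- c("semmed", "kegg", "uniprot", "pharmgkb")

# per-source surface decoration of a canonical entity term; each variant
# normalizes to a distinct lexicon term, and the generated lexicon carries
# every variant, so concept resolution is exact by construction
decorate_entity <- function(term, source) {
  base <- gsub(" ", "_", term, fixed = TRUE)
  switch(source,
         semmed = toupper(base),
         kegg = paste0(base, "_kg"),
         uniprot = paste0(base, "_up"),
         pharmgkb = toupper(paste0(base, "_pg")))
}

decorate_predicate <- function(local, source) {
  # casing varies by source; normalization case-folds, so all variants share
  # the vocabulary predicate's concept
  switch(source,
         semmed = toupper(local),
         kegg = local,
         uniprot = toupper(local),
         pharmgkb = local)
}

synth_entity_ns <- function(source) sprintf("http://example.org/%s/ENTITY#", source)
synth_predicate_ns <- function(source) sprintf("http://example.org/%s/PREDICATE#", source)

#' Configuration for the toy knowledge-graph generator
#'
#' Defaults emulate a desk-scale four-source corpus: tens of entities per
#' class, a few dozen assertions per source, and a moderate cross-dataset
#' duplication rate. `p_dup` is the probability that an assertion is also
#' asserted (under different surface forms) by a second, randomly chosen
#' source — these duplications are the planted cross-dataset links.
#'
#' @param n_genes,n_drugs,n_disorders entity counts per class
#' @param n_triples_per_source assertion triples drawn per source
#' @param p_dup duplication probability in `[0, 1]`
#' @param seed integer RNG seed; identical configs and seeds give
#'   byte-identical output files
#' @param vocabulary a `PredicateVocabulary` (defaults to
#'   [packaged_vocabulary()])
#' @return a `SynthConfig` list
#' @export
synth_config <- function(n_genes = 20, n_drugs = 10, n_disorders = 10,
                         n_triples_per_source = 50, p_dup = 0.3, seed = 1,
                         vocabulary = packaged_vocabulary()) {
  stopifnot(n_genes >= 0, n_drugs >= 0, n_disorders >= 0,
            n_triples_per_source >= 0, p_dup >= 0, p_dup <= 1)
  structure(list(n_genes = n_genes, n_drugs = n_drugs, n_disorders = n_disorders,
                 n_triples_per_source = n_triples_per_source, p_dup = p_dup,
                 seed = as.integer(seed), vocabulary = vocabulary),
            class = "SynthConfig")
}

# admissible (subject class, object class) pairs per vocabulary predicate,
# derived from its group memberships (group k serves pattern Qk)
admissible_pairs <- function(vocabulary) {
  pats <- query_patterns()
  out <- stats::setNames(vector("list", length(vocabulary$entries)),
                         names(vocabulary$entries))
  for (g in names(vocabulary$groups)) {
    q <- names(vocabulary$pattern_to_group)[vocabulary$pattern_to_group == g]
    row <- pats[pats$id == q]
    for (rid in vocabulary$groups[[g]]) {
      out[[rid]] <- rbind(out[[rid]], c(row$seed_class, row$target_class))
    }
  }
  for (rid in names(vocabulary$ungrouped_pairs)) {
    if (rid %in% names(out) && is.null(out[[rid]])) {
      out[[rid]] <- rbind(out[[rid]], vocabulary$ungrouped_pairs[[rid]])
    }
  }
  out
}

#' Generate a seeded four-source toy knowledge graph
#'
#' Creates four namespaced triple stores sharing one entity population under
#' source-specific surface forms, a concept lexicon covering every surface
#' form and predicate term, `rdf:type` and label triples for every
#' referenced entity, and assertion triples drawn from the packaged
#' 25-predicate vocabulary restricted to class-compatible endpoints. Each
#' assertion is duplicated into a second source with probability `p_dup`;
#' duplications are recorded as planted links. Distinct assertions are kept
#' concept-wise unique across sources so that the planted links are exactly
#' the links a correct miner should find.
#'
#' @param config a `SynthConfig`
#' @return list with `stores` (named list of four `TripleStore`s),
#'   `lexicon` (`ConceptLexicon`) and `truth` (list: `planted_links`
#'   (`LinkSet`), `entity_classes`, `expected_relsets`, `answer_key`,
#'   `config`)
#' @export
generate_toy_kg <- function(config = synth_config()) {
  stopifnot(inherits(config, "SynthConfig"))
  vocab <- config$vocabulary
  pairs_of <- admissible_pairs(vocab)

  # entity registry: one CUI and canonical term per entity
  reg <- data.table::rbindlist(list(
    if (config$n_genes) data.table::data.table(class = "gene", idx = seq_len(config$n_genes)),
    if (config$n_drugs) data.table::data.table(class = "drug", idx = seq_len(config$n_drugs)),
    if (config$n_disorders) data.table::data.table(class = "disorder", idx = seq_len(config$n_disorders))
  ))
  lex_terms <- character(); lex_cuis <- character(); lex_classes <- character()
  ent <- list()  # class -> data.table(idx, cui, term, label)
  if (nrow(reg)) {
    reg[, cui := sprintf("C%07d", .I)]
    reg[, term := paste(class, idx)]
    reg[, label := paste(paste0(toupper(substr(class, 1, 1)),
                                substr(class, 2, nchar(class))), idx)]
    for (src in SYNTH_SOURCES) {
      lex_terms <- c(lex_terms, decorate_entity(reg$term, src))
      lex_cuis <- c(lex_cuis, reg$cui)
      lex_classes <- c(lex_classes, reg$class)
    }
    ent <- split(reg, reg$class)
  }
  # predicate concepts: one CUI per vocabulary entry, keyed by its term
  pred_cui <- stats::setNames(sprintf("CP%05d", seq_along(vocab$entries)),
                              names(vocab$entries))
  lex_terms <- c(lex_terms, local_name(unname(vocab$entries)))
  lex_cuis <- c(lex_cuis, unname(pred_cui))
  lex_classes <- c(lex_classes, rep(NA_character_, length(pred_cui)))
  lexicon <- concept_lexicon(lex_terms, lex_cuis, lex_classes)

  ent_uri <- function(class, idx, src) {
    row <- ent[[class]][idx]
    paste0(synth_entity_ns(src), decorate_entity(row$term, src))
  }
  pred_uri <- function(rid, src) {
    paste0(synth_predicate_ns(src), decorate_predicate(local_name(vocab$entries[[rid]]), src))
  }

  used_keys <- new.env(parent = emptyenv())  # global CUI-signature registry
  asserts <- stats::setNames(rep(list(list()), length(SYNTH_SOURCES)), SYNTH_SOURCES)
  referenced <- stats::setNames(rep(list(data.table::data.table(class = character(),
                                                                idx = integer())),
                                    length(SYNTH_SOURCES)), SYNTH_SOURCES)
  planted <- list()
  relset_book <- stats::setNames(rep(list(character()), 9L), relation_keys())

  set.seed(config$seed)
  source_seeds <- sample.int(.Machine$integer.max - 1L, length(SYNTH_SOURCES))

  for (si in seq_along(SYNTH_SOURCES)) {
    src <- SYNTH_SOURCES[si]
    set.seed(source_seeds[si])
    rids <- names(vocab$entries)
    cycle <- character(0)
    for (j in seq_len(config$n_triples_per_source)) {
      if (!length(cycle)) cycle <- sample(rids)  # coverage: reshuffled cycles
      rid <- cycle[1L]; cycle <- cycle[-1L]
      pairs <- pairs_of[[rid]]
      if (is.null(pairs)) next
      pair <- pairs[sample.int(nrow(pairs), 1L), ]
      scl <- pair[1L]; ocl <- pair[2L]
      if (is.null(ent[[scl]]) || is.null(ent[[ocl]])) next
      placed <- FALSE
      for (att in 1:50) {
        sidx <- sample.int(nrow(ent[[scl]]), 1L)
        oidx <- sample.int(nrow(ent[[ocl]]), 1L)
        if (scl == ocl && sidx == oidx) next
        key <- paste(ent[[scl]]$cui[sidx], pred_cui[[rid]], ent[[ocl]]$cui[oidx], sep = "\r")
        if (!is.null(used_keys[[key]])) next
        used_keys[[key]] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) next
      left <- list(subject = ent_uri(scl, sidx, src), predicate = pred_uri(rid, src),
                   object = ent_uri(ocl, oidx, src), source = src)
      asserts[[src]][[length(asserts[[src]]) + 1L]] <- left
      referenced[[src]] <- data.table::rbindlist(list(
        referenced[[src]],
        data.table::data.table(class = c(scl, ocl), idx = c(sidx, oidx))))
      relset_book[[paste0(scl, "2", ocl)]] <-
        unique(c(relset_book[[paste0(scl, "2", ocl)]], left$predicate))
      if (config$p_dup > 0 && stats::runif(1) < config$p_dup) {
        other <- sample(setdiff(SYNTH_SOURCES, src), 1L)
        right <- list(subject = ent_uri(scl, sidx, other), predicate = pred_uri(rid, other),
                      object = ent_uri(ocl, oidx, other), source = other)
        asserts[[other]][[length(asserts[[other]]) + 1L]] <- right
        referenced[[other]] <- data.table::rbindlist(list(
          referenced[[other]],
          data.table::data.table(class = c(scl, ocl), idx = c(sidx, oidx))))
        relset_book[[paste0(scl, "2", ocl)]] <-
          unique(c(relset_book[[paste0(scl, "2", ocl)]], right$predicate))
        planted[[length(planted) + 1L]] <- data.table::data.table(
          left_subject = left$subject, left_predicate = left$predicate,
          left_object = left$object, left_source = left$source,
          right_subject = right$subject, right_predicate = right$predicate,
          right_object = right$object, right_source = right$source,
          subject_cui = ent[[scl]]$cui[sidx], predicate_cui = pred_cui[[rid]],
          object_cui = ent[[ocl]]$cui[oidx])
      }
    }
  }

  stores <- list()
  entity_classes <- character()
  for (src in SYNTH_SOURCES) {
    adt <- if (length(asserts[[src]])) data.table::rbindlist(asserts[[src]]) else NULL
    ref <- unique(referenced[[src]])
    extra <- NULL
    if (nrow(ref)) {
      data.table::setorderv(ref, c("class", "idx"))
      uris <- vapply(seq_len(nrow(ref)), function(i) ent_uri(ref$class[i], ref$idx[i], src),
                     character(1))
      labels <- vapply(seq_len(nrow(ref)), function(i) ent[[ref$class[i]]]$label[ref$idx[i]],
                       character(1))
      entity_classes[uris] <- ref$class
      extra <- data.table::rbindlist(list(
        data.table::data.table(subject = uris, predicate = KG_RDF_TYPE,
                               object = kg_class_uri(ref$class), literal = FALSE),
        data.table::data.table(subject = uris, predicate = kg_label_predicate(),
                               object = labels, literal = TRUE)
      ))
      extra[, source := src]
    }
    dt <- NULL
    if (!is.null(adt)) {
      adt[, literal := FALSE]
      adt <- adt[, c("subject", "predicate", "object", "literal", "source"), with = FALSE]
      dt <- adt
    }
    if (!is.null(extra)) dt <- data.table::rbindlist(list(dt, extra), use.names = TRUE)
    store <- triple_store(dt)
    if (is.null(store$namespaces[[src]])) store$namespaces[[src]] <- character()
    stores[[src]] <- store
  }

  planted_links <- empty_linkset()
  if (length(planted)) planted_links$links <- canonical_links(data.table::rbindlist(planted))

  expected_relsets <- structure(lapply(relset_book, sort), unclassified = 0L,
                                class = c("RelationSets", "list"))

  merged <- merge_stores(unname(stores))
  answer_key <- list()
  for (qi in seq_len(nrow(query_patterns()))) {
    pat <- query_patterns()[qi]
    cls_ent <- ent[[pat$seed_class]]
    if (is.null(cls_ent) || !nrow(cls_ent)) next
    seed_label <- cls_ent$label[1L]
    answer_key[[paste0(pat$id, "|", seed_label)]] <-
      oracle_query(merged, expected_relsets, pat$id, seed_label,
                   classes = entity_classes, lexicon = lexicon)
  }

  list(stores = stores, lexicon = lexicon,
       truth = list(planted_links = planted_links, entity_classes = entity_classes,
                    expected_relsets = expected_relsets, answer_key = answer_key,
                    config = config))
}

#' Write a generated toy knowledge graph to disk
#'
#' Writes one N-Triples file per source, the lexicon (`cui.tsv`), an entity
#' class map (`classes.tsv`), a dataset manifest (`datasets.yaml`) and the
#' ground truth (`truth.json`). Output is byte-identical for identical
#' configs.
#'
#' @param kg result of [generate_toy_kg()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_toy_kg <- function(kg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(datasets = list())
  for (src in names(kg$stores)) {
    f <- paste0(src, ".nt")
    write_ntriples(kg$stores[[src]], file.path(outdir, f))
    manifest$datasets[[length(manifest$datasets) + 1L]] <-
      list(dataset_id = src, path = f, format = "ntriples")
  }
  yaml::write_yaml(manifest, file.path(outdir, "datasets.yaml"))
  write_lexicon(kg$lexicon, file.path(outdir, "cui.tsv"))
  cls <- kg$truth$entity_classes
  writeLines(paste(names(cls), unname(cls), sep = "\t"), file.path(outdir, "classes.tsv"),
             useBytes = TRUE)
  truth <- list(
    planted_links = as.data.frame(kg$truth$planted_links$links),
    entity_classes = as.list(kg$truth$entity_classes),
    expected_relsets = lapply(unclass(kg$truth$expected_relsets), as.character),
    answer_key = kg$truth$answer_key
  )
  jsonlite::write_json(truth, file.path(outdir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(outdir)
}

# ---- brute-force oracles ----------------------------------------------------

#' Brute-force link oracle
#'
#' Exhaustively evaluates the linking condition over all triple pairs of the
#' merged input: component-wise CUI resolution of each triple, equality of
#' the three CUIs, and a namespace difference on subject or object. Intended
#' for small stores in tests; shares no code with [mine_links()]'s indexed
#' enumeration.
#'
#' @param stores list of `TripleStore`s (or a single merged store)
#' @param lexicon a `ConceptLexicon`
#' @return a `LinkSet`
#' @export
oracle_links <- function(stores, lexicon) {
  if (inherits(stores, "TripleStore")) stores <- list(stores)
  dt <- data.table::rbindlist(lapply(stores, function(s) s$triples),
                              use.names = TRUE, fill = TRUE)
  out <- empty_linkset()
  if (!nrow(dt)) return(out)
  scui <- cui_of(lexicon, dt$subject)
  pcui <- cui_of(lexicon, dt$predicate)
  ocui <- cui_of(lexicon, dt$object)
  sns <- namespace_of(dt$subject)
  ons <- ifelse(dt$literal, "", namespace_of(dt$object))
  rows <- list()
  seen <- new.env(parent = emptyenv())
  n <- nrow(dt)
  for (i in seq_len(n - 1L)) {
    if (is.na(scui[i]) || is.na(pcui[i]) || is.na(ocui[i])) next
    for (j in (i + 1L):n) {
      if (is.na(scui[j]) || is.na(pcui[j]) || is.na(ocui[j])) next
      if (scui[i] != scui[j] || pcui[i] != pcui[j] || ocui[i] != ocui[j]) next
      if (sns[i] == sns[j] && ons[i] == ons[j]) next
      ti <- paste(dt$subject[i], dt$predicate[i], dt$object[i], dt$source[i], sep = "\r")
      tj <- paste(dt$subject[j], dt$predicate[j], dt$object[j], dt$source[j], sep = "\r")
      a <- if (ti <= tj) i else j
      b <- if (ti <= tj) j else i
      pk <- paste(min(ti, tj), max(ti, tj), sep = "\n")
      if (!is.null(seen[[pk]])) next
      seen[[pk]] <- TRUE
      rows[[length(rows) + 1L]] <- data.table::data.table(
        left_subject = dt$subject[a], left_predicate = dt$predicate[a],
        left_object = dt$object[a], left_source = dt$source[a],
        right_subject = dt$subject[b], right_predicate = dt$predicate[b],
        right_object = dt$object[b], right_source = dt$source[b],
        subject_cui = scui[a], predicate_cui = pcui[a], object_cui = ocui[a])
    }
  }
  if (length(rows)) {
    links <- data.table::rbindlist(rows)
    data.table::setorderv(links, names(links))
    out$links <- links
  }
  out
}

#' Brute-force query oracle
#'
#' Full linear-scan implementation of the resolve / traverse / class-filter
#' query, with no indexing and no shared traversal code with
#' [run_pattern()]. Returns the expected hit key set (CUIs where resolvable,
#' else URIs).
#'
#' @param store merged `TripleStore`
#' @param relsets a `RelationSets`
#' @param pattern_id `"Q1"`..`"Q9"`
#' @param seed_label seed entity label
#' @param classes named URI -> class map; derived by scanning `rdf:type`
#'   triples when omitted
#' @param lexicon optional `ConceptLexicon` for concept-level dedup
#' @return sorted character vector of hit keys
#' @export
oracle_query <- function(store, relsets, pattern_id, seed_label,
                         classes = NULL, lexicon = NULL) {
  pat <- query_patterns()[query_patterns()$id == pattern_id]
  stopifnot(nrow(pat) == 1L)
  dt <- store$triples
  if (is.null(classes)) {
    classes <- character()
    for (i in seq_len(nrow(dt))) {
      if (dt$predicate[i] == KG_RDF_TYPE && !dt$literal[i]) {
        cls <- class_from_uri(dt$object[i])
        if (!is.na(cls)) classes[dt$subject[i]] <- cls
      }
    }
  }
  want <- normalize_term(seed_label)
  seeds <- character()
  for (i in seq_len(nrow(dt))) {
    if (dt$predicate[i] == kg_label_predicate() && dt$literal[i] &&
        normalize_term(dt$object[i]) == want) {
      seeds <- c(seeds, dt$subject[i])
    }
  }
  seeds <- unique(seeds)
  if (!length(seeds)) return(character())
  preds <- relsets[[pat$relation_key]]
  keyify <- function(u) {
    if (is.null(lexicon)) return(u)
    k <- cui_of(lexicon, u)
    ifelse(is.na(k), u, k)
  }
  temp <- character(); reflexive <- character()
  for (i in seq_len(nrow(dt))) {
    if (dt$literal[i]) next
    if (!(dt$subject[i] %in% seeds)) next
    if (!(dt$predicate[i] %in% preds)) next
    cls <- classes[dt$object[i]]
    if (is.na(cls) || cls != pat$target_class) next
    k <- keyify(dt$object[i])
    temp <- c(temp, k)
    if (dt$subject[i] == dt$object[i]) reflexive <- c(reflexive, k)
  }
  seed_keys <- unique(keyify(seeds))
  sort(unique(setdiff(temp, setdiff(seed_keys, reflexive))))
}
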