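#' The packaged 25-predicate vocabulary and its nine relationship groups
#'
#' The package ships the reference vocabulary of 25 predicates (R1..R25)
#' observed across the four emulated sources (a literature predication
#' store, a pathway database, a protein database and a pharmacogenomics
#' database), together with the nine predicate relationship groups
#' (PRG1..PRG9), one per query pattern Q1..Q9. For example PRG6, serving
#' "all drugs treating a disorder", is {R13, R21}; R13
#' (`pharmgkb:associated`) is the generic association predicate and belongs
#' to all nine groups.
#'
#' @return an object of class `PredicateVocabulary` with fields:
#'   `entries` (named character, R-id -> absolute predicate URI),
#'   `prefixed` (named character, R-id -> prefixed name as usually printed),
#'   `groups` (named list, PRG-id -> character vector of R-ids),
#'   `ungrouped_pairs` (named list, R-id -> c(subject class, object class)
#'   for the three predicates that belong to no group),
#'   `pattern_to_group` (named character, Q-id -> PRG-id).
#' @examples
#' vocab <- packaged_vocabulary()
#' length(vocab$entries)   # 25
#' vocab$groups$PRG6       # "R13" "R21"
#' @export
packaged_vocabulary <- function() {
  ns <- c(
    sem = "http://www4.wiwiss.fu-berlin.de/semdb/PREDICATE#",
    kegg = "http://www4.wiwiss.fu-berlin.de/kegg/PREDICATE#",
    uniprot = "http://www4.wiwiss.fu-berlin.de/uniprot/PREDICATE#",
    pharmgkb = "http://www4.wiwiss.fu-berlin.de/pharmgkb/PREDICATE#"
  )
  prefixed <- c(
    R1 = "sem:coexists_with", R2 = "sem:interacts_with", R3 = "sem:causes",
    R4 = "sem:prevents", R5 = "sem:manifestation_of", R6 = "sem:affects",
    R7 = "sem:occurs_in", R8 = "sem:associated_with", R9 = "kegg:hasDisease",
    R10 = "kegg:hasDrug", R11 = "uniprot:externalLink", R12 = "pharmgkb:Related_Genes",
    R13 = "pharmgkb:associated", R14 = "sem:stimulates", R15 = "sem:inhibits",
    R16 = "sem:disrupts", R17 = "sem:treats", R18 = "sem:complicates",
    R19 = "sem:predisposes", R20 = "sem:augments", R21 = "sem:produces",
    R22 = "kegg:hasPathway", R23 = "kegg:hasGene", R24 = "pharmgkb:Related_Drugs",
    R25 = "pharmgkb:c2b2r_Related_Diseases"
  )
  pfx <- sub(":.*$", "", prefixed)
  loc <- sub("^[^:]*:", "", prefixed)
  entries <- stats::setNames(paste0(ns[pfx], loc), names(prefixed))
  groups <- list(
    PRG1 = c("R1", "R2", "R11", "R13", "R14", "R22", "R23"),
    PRG2 = c("R1", "R2", "R3", "R13", "R14", "R15", "R21"),
    PRG3 = c("R3", "R6", "R8", "R13", "R16", "R19"),
    PRG4 = c("R1", "R2", "R13", "R14", "R15", "R22"),
    PRG5 = c("R2", "R13", "R14", "R15"),
    PRG6 = c("R13", "R21"),
    PRG7 = c("R1", "R2", "R5", "R6", "R7", "R13", "R18", "R19", "R20"),
    PRG8 = c("R3", "R4", "R13", "R17", "R25"),
    PRG9 = c("R8", "R12", "R13")
  )
  # R9, R10 and R24 belong to no group; their endpoint classes follow their
  # names (hasDisease: gene->disorder, hasDrug: disorder->drug,
  # Related_Drugs: drug->drug) so generators can still emit them
  ungrouped_pairs <- list(
    R9 = c("gene", "disorder"),
    R10 = c("disorder", "drug"),
    R24 = c("drug", "drug")
  )
  structure(list(
    entries = entries,
    prefixed = prefixed,
    namespaces = ns,
    groups = groups,
    ungrouped_pairs = ungrouped_pairs,
    pattern_to_group = stats::setNames(paste0("PRG", 1:9), paste0("Q", 1:9))
  ), class = "PredicateVocabulary")
}

#' The nine directed query patterns
#'
#' Q1..Q9 cover every ordered pair of the three entity classes: each pattern
#' has a seed class (the class of the entity named by the user) and a target
#' class (the class of the returned entities), e.g. Q6 asks for all drugs
#' treating a given disorder (seed disorder, target drug).
#'
#' @return data.table with columns `id`, `seed_class`, `target_class`,
#'   `relation_key` (e.g. `"disorder2drug"`) and `description`
#' @export
query_patterns <- function() {
  dt <- data.table::data.table(
    id = paste0("Q", 1:9),
    seed_class = c("gene", "gene", "gene", "disorder", "disorder", "disorder",
                   "drug", "drug", "drug"),
    target_class = c("gene", "disorder", "drug", "disorder", "gene", "drug",
                     "drug", "disorder", "gene"),
    description = c(
      "all genes related to a specific gene",
      "all disorders caused by a specific gene",
      "all drugs targeting a specific gene",
      "all disorders related to a specific disorder",
      "all genes causing a specific disorder",
      "all drugs treating a specific disorder",
      "all drugs related to a specific drug",
      "all disorders treated by a specific drug",
      "all genes targeted by a specific drug"
    )
  )
  dt[, relation_key := paste0(seed_class, "2", target_class)]
  dt[]
}

relation_keys <- function() query_patterns()$relation_key

#' Assign gene/drug/disorder classes to entities
#'
#' Class evidence is taken in priority order: an explicit
#' `rdf:type myclass:Gene/Drug/Disorder` triple; else the lexicon's CUI
#' class; else an optional URI/CUI class-map file (TSV `uri_or_cui<TAB>class`).
#' Entities with no evidence stay unclassified (absent from the result).
#' Two conflicting `rdf:type` assertions for one URI raise an error naming
#' the URI; a lower-priority disagreement is silently overridden.
#'
#' @param store a `TripleStore`
#' @param lexicon optional `ConceptLexicon` supplying CUI classes
#' @param class_map optional path to a TSV class-map file
#' @return named character vector, URI -> class
#' @export
assign_classes <- function(store, lexicon = NULL, class_map = NULL) {
  dt <- store$triples
  out <- character()

  # lowest priority: class-map file
  if (!is.null(class_map)) {
    lines <- readLines(class_map, warn = FALSE, encoding = "UTF-8")
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      keys <- vapply(parts, `[`, character(1), 1L)
      vals <- vapply(parts, `[`, character(1), 2L)
      stopifnot(all(vals %in% c(KG_CLASSES, "other")))
      ents <- unique(c(dt[!dt$literal]$object, dt$subject))
      by_uri <- stats::setNames(vals, keys)[ents]
      hit <- !is.na(by_uri) & by_uri %in% KG_CLASSES
      out[ents[hit]] <- by_uri[hit]
      if (!is.null(lexicon)) {
        ecui <- cui_of(lexicon, ents)
        by_cui <- stats::setNames(vals, keys)[ecui]
        hit <- !is.na(by_cui) & by_cui %in% KG_CLASSES
        out[ents[hit]] <- by_cui[hit]
      }
    }
  }

  # middle priority: lexicon CUI classes
  if (!is.null(lexicon) && length(lexicon$cui_to_class)) {
    ents <- unique(c(dt$subject, dt[!dt$literal]$object))
    cls <- class_of_cui(lexicon, cui_of(lexicon, ents))
    hit <- !is.na(cls) & cls %in% KG_CLASSES
    out[ents[hit]] <- cls[hit]
  }

  # top priority: explicit rdf:type triples
  ty <- dt[dt$predicate == KG_RDF_TYPE & !dt$literal]
  if (nrow(ty)) {
    cls <- class_from_uri(ty$object)
    ty <- ty[!is.na(cls)]
    cls <- cls[!is.na(cls)]
    if (nrow(ty)) {
      per_uri <- tapply(cls, ty$subject, function(v) unique(v))
      bad <- names(per_uri)[vapply(per_uri, length, integer(1)) > 1L]
      if (length(bad)) {
        stop(sprintf("conflicting rdf:type classes for: %s",
                     paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
      }
      out[names(per_uri)] <- vapply(per_uri, `[`, character(1), 1L)
    }
  }
  out
}

#' Partition predicate occurrences into the nine directed relation sets
#'
#' Walks every triple whose subject and object are both classified and adds
#' its predicate to the relation set keyed by (subject class, object class):
#' `gene2gene`, `gene2drug`, ... `disorder2drug`. Sets are directed and may
#' overlap (one predicate can occur between several class pairs). Triples
#' with an unclassified endpoint are counted and reported via the
#' `unclassified` attribute, not classified.
#'
#' @param store a `TripleStore`
#' @param classes named character vector from [assign_classes()]
#' @return an object of class `RelationSets`: named list of nine character
#'   vectors of predicate URIs (possibly empty), with attribute
#'   `unclassified` (number of skipped triples with >=1 unclassified
#'   endpoint among non-literal, non-label/type triples)
#' @export
classify_relations <- function(store, classes) {
  keys <- relation_keys()
  sets <- stats::setNames(rep(list(character()), length(keys)), keys)
  dt <- store$triples[!store$triples$literal &
                        store$triples$predicate != KG_RDF_TYPE &
                        store$triples$predicate != kg_label_predicate()]
  n_unclassified <- 0L
  if (nrow(dt)) {
    scls <- unname(classes[dt$subject])
    ocls <- unname(classes[dt$object])
    ok <- !is.na(scls) & !is.na(ocls)
    n_unclassified <- sum(!ok)
    if (any(ok)) {
      key <- paste0(scls[ok], "2", ocls[ok])
      pred <- dt$predicate[ok]
      for (k in unique(key)) {
        sets[[k]] <- sort(unique(pred[key == k]))
      }
    }
  }
  structure(sets, unclassified = n_unclassified, class = c("RelationSets", "list"))
}

#' Write relation sets as JSON
#' @param relsets a `RelationSets`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_relsets <- function(relsets, path) {
  jsonlite::write_json(lapply(unclass(relsets), as.character), path, pretty = TRUE)
  invisible(path)
}

#' Read relation sets from JSON
#' @param path JSON path written by [write_relsets()]
#' @return a `RelationSets`
#' @export
read_relsets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- relation_keys()
  sets <- stats::setNames(rep(list(character()), length(keys)), keys)
  for (k in intersect(names(raw), keys)) sets[[k]] <- as.character(raw[[k]])
  structure(sets, unclassified = 0L, class = c("RelationSets", "list"))
}
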