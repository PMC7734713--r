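#' Annotate a store's triples with CUIs
#'
#' Adds `subject_cui`, `predicate_cui` and `object_cui` columns, each
#' resolved through the lexicon (URI local name, normalized, looked up) and
#' `NA` where unresolved. Literal objects resolve only if their lexical form
#' matches a lexicon term. Store content is otherwise unchanged.
#'
#' @param store a `TripleStore`
#' @param lexicon a `ConceptLexicon`
#' @return the store with CUI columns on its triple table
#' @export
annotate_cuis <- function(store, lexicon) {
  dt <- store$triples
  if (nrow(dt)) {
    dt[, subject_cui := cui_of(lexicon, subject)]
    dt[, predicate_cui := cui_of(lexicon, predicate)]
    dt[, object_cui := cui_of(lexicon, object)]
  } else {
    dt[, `:=`(subject_cui = character(), predicate_cui = character(),
              object_cui = character())]
  }
  store
}

empty_linkset <- function() {
  structure(list(links = data.table::data.table(
    left_subject = character(), left_predicate = character(), left_object = character(),
    left_source = character(),
    right_subject = character(), right_predicate = character(), right_object = character(),
    right_source = character(),
    subject_cui = character(), predicate_cui = character(), object_cui = character()
  )), class = "LinkSet")
}

#' @export
print.LinkSet <- function(x, ...) {
  cat(sprintf("<LinkSet: %d link(s)>\n", nrow(x$links)))
  invisible(x)
}

#' Number of links in a link set
#' @param links a `LinkSet`
#' @return integer count
#' @export
n_links <- function(links) nrow(links$links)

# canonical orientation for an unordered pair of triples: lexicographically
# smaller (subject, predicate, object, source) tuple becomes "left"
canonical_links <- function(dt) {
  if (!nrow(dt)) return(dt)
  lkey <- paste(dt$left_subject, dt$left_predicate, dt$left_object, dt$left_source, sep = "\r")
  rkey <- paste(dt$right_subject, dt$right_predicate, dt$right_object, dt$right_source, sep = "\r")
  swap <- rkey < lkey
  if (any(swap)) {
    for (f in c("subject", "predicate", "object", "source")) {
      l <- paste0("left_", f); r <- paste0("right_", f)
      tmp <- dt[[l]][swap]
      data.table::set(dt, which(swap), l, dt[[r]][swap])
      data.table::set(dt, which(swap), r, tmp)
    }
  }
  dt <- unique(dt, by = c("left_subject", "left_predicate", "left_object", "left_source",
                          "right_subject", "right_predicate", "right_object", "right_source"))
  data.table::setorderv(dt, names(dt))
  dt
}

#' Mine cross-dataset links between concept-equal assertions
#'
#' Two triples form a link when their subject CUIs agree, their predicate
#' CUIs agree (directly or through the predicate alias groups produced by
#' [extend_predicates()]), their object CUIs agree, and the namespace of the
#' subject or of the object differs — i.e. two sources assert the same
#' conceptual statement about entities written under different names. Pairs
#' with any unresolved CUI never link. Links are unordered pairs, returned
#' in canonical orientation.
#'
#' Enumeration goes through the predicate-subject-object index per predicate
#' alias group and per (subject CUI, object CUI) bucket rather than over all
#' triple pairs.
#'
#' @param stores list of two or more `TripleStore` objects (or one merged
#'   store passed as a single-element list along with distinct namespaces)
#' @param lexicon a `ConceptLexicon`
#' @return a `LinkSet`
#' @export
mine_links <- function(stores, lexicon) {
  if (inherits(stores, "TripleStore")) stores <- list(stores)
  merged <- if (length(stores) == 1L) stores[[1L]] else merge_stores(stores)
  if (length(stores) < 2L &&
      (length(stores) == 0L || length(merged$namespaces) < 2L)) {
    stop("mine_links needs datasets from at least two sources", call. = FALSE)
  }
  merged <- build_pso_index(merged)
  merged <- annotate_cuis(merged, lexicon)
  dt <- merged$triples
  out <- empty_linkset()
  cand <- dt[!is.na(dt$subject_cui) & !is.na(dt$predicate_cui) & !is.na(dt$object_cui)]
  if (!nrow(cand)) return(out)
  # bucket by full CUI signature; alias-group predicate matching is implied
  # because aliases share the predicate CUI
  cand[, sig := paste(subject_cui, predicate_cui, object_cui, sep = "\r")]
  cand[, sub_ns := namespace_of(subject)]
  cand[, obj_ns := ifelse(literal, "", namespace_of(object))]
  res <- list()
  for (g in split(seq_len(nrow(cand)), cand$sig)) {
    if (length(g) < 2L) next
    pairs <- utils::combn(g, 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      if (cand$sub_ns[i] != cand$sub_ns[j] || cand$obj_ns[i] != cand$obj_ns[j]) {
        res[[length(res) + 1L]] <- data.table::data.table(
          left_subject = cand$subject[i], left_predicate = cand$predicate[i],
          left_object = cand$object[i], left_source = cand$source[i],
          right_subject = cand$subject[j], right_predicate = cand$predicate[j],
          right_object = cand$object[j], right_source = cand$source[j],
          subject_cui = cand$subject_cui[i], predicate_cui = cand$predicate_cui[i],
          object_cui = cand$object_cui[i]
        )
      }
    }
  }
  if (length(res)) out$links <- canonical_links(data.table::rbindlist(res))
  out
}

#' Materialize mined links into a store
#'
#' For every link adds up to three bridge assertions under the reserved
#' source id `"kgtrio"`: `left.subject sameConcept right.subject`,
#' `left.object sameConcept right.object` (identity pairs are skipped), and
#' the cross-namespace assertion `left.subject left.predicate right.object`.
#' Existing triples are never modified and re-materializing adds nothing.
#'
#' @param store a `TripleStore` (typically the merged store)
#' @param links a `LinkSet` mined from the same store family
#' @return the augmented store
#' @export
materialize_links <- function(store, links) {
  dt <- links$links
  if (!nrow(dt)) return(store)
  same <- kg_same_concept_predicate()
  new <- data.table::rbindlist(list(
    data.table::data.table(subject = dt$left_subject, predicate = same,
                           object = dt$right_subject),
    data.table::data.table(subject = dt$left_object, predicate = same,
                           object = dt$right_object),
    data.table::data.table(subject = dt$left_subject, predicate = dt$left_predicate,
                           object = dt$right_object)
  ))
  new <- new[new$subject != new$object | new$predicate != same]
  new[, literal := FALSE]
  new[, source := "kgtrio"]
  add_triples(store, unique(new))
}

#' Write a link set as TSV
#' @param links a `LinkSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_links <- function(links, path) {
  cols <- c("left_subject", "left_predicate", "left_object",
            "right_subject", "right_predicate", "right_object",
            "subject_cui", "predicate_cui", "object_cui")
  dt <- links$links[, cols, with = FALSE]
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(dt)) do.call(paste, c(as.list(dt), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Integrate a family of RDF datasets into one linked store
#'
#' Runs the full integration pipeline: load every dataset in the manifest,
#' merge with provenance, build the predicate-subject-object index, annotate
#' CUIs, extend the predicate set with concept aliases, mine cross-dataset
#' links and materialize them as bridge triples.
#'
#' @param manifest path to a dataset manifest (see [read_manifest()]) or a
#'   pre-parsed list of dataset descriptors
#' @param lexicon_path path to a lexicon TSV, or a `ConceptLexicon`
#' @return list with fields `store` (augmented merged `TripleStore`),
#'   `links` (`LinkSet`), `alias_table` (`PredicateAliasTable`),
#'   `link_counts` (data.table of link counts per unordered source pair) and
#'   `mined_relationship_types` (number of distinct predicate concepts
#'   participating in at least one link)
#' @export
integrate_datasets <- function(manifest, lexicon_path) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  entries <- stage("manifest", {
    if (is.character(manifest)) read_manifest(manifest) else manifest
  })
  lexicon <- stage("lexicon", {
    if (inherits(lexicon_path, "ConceptLexicon")) lexicon_path else load_lexicon(lexicon_path)
  })
  stores <- stage("load", {
    lapply(entries, function(e) load_rdf(e$path, e$format, e$dataset_id))
  })
  merged <- stage("merge", merge_stores(stores))
  merged <- stage("index", build_pso_index(merged))
  merged <- stage("annotate", annotate_cuis(merged, lexicon))
  alias_table <- stage("extend_predicates",
                       extend_predicates(unique(merged$triples$predicate), lexicon))
  links <- stage("mine_links", mine_links(list(merged), lexicon))
  augmented <- stage("materialize", materialize_links(merged, links))
  ldt <- links$links
  counts <- if (nrow(ldt)) {
    pair <- ifelse(ldt$left_source <= ldt$right_source,
                   paste(ldt$left_source, ldt$right_source, sep = "~"),
                   paste(ldt$right_source, ldt$left_source, sep = "~"))
    tab <- table(pair)
    data.table::data.table(source_pair = names(tab), links = as.integer(tab))
  } else {
    data.table::data.table(source_pair = character(), links = integer())
  }
  list(store = augmented, links = links, alias_table = alias_table,
       link_counts = counts,
       mined_relationship_types = length(unique(ldt$predicate_cui)))
}
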