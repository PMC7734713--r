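#' Normalize a surface form
#'
#' Case-folds, maps underscores and hyphens to spaces, trims surrounding
#' whitespace and collapses internal whitespace runs to single spaces.
#' Idempotent. This is the only string normalization applied anywhere in the
#' package: concept matching is exact after normalization, never fuzzy.
#'
#' @param raw character vector
#' @return normalized character vector
#' @examples
#' normalize_term("COEXISTS_WITH")   # "coexists with"
#' normalize_term("  Parkinson's  ") # "parkinson's"
#' @export
normalize_term <- function(raw) {
  x <- tolower(raw)
  x <- gsub("[_-]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Build a concept lexicon
#'
#' A `ConceptLexicon` maps normalized surface forms to concept unique
#' identifiers (CUIs) and back, playing the role a concept metathesaurus
#' plays for real biomedical vocabularies: synonymous terms share one CUI.
#' A term may map to at most one CUI; rows assigning one normalized term to
#' two CUIs (polysemy) are rejected.
#'
#' @param terms character vector of surface forms
#' @param cuis character vector of CUIs, parallel to `terms`
#' @param classes optional character vector of entity classes per row
#'   (`gene`/`drug`/`disorder`/`other`, NA allowed)
#' @return an object of class `ConceptLexicon` with fields `term_to_cui`
#'   (named character), `cui_to_terms` (named list of character) and
#'   `cui_to_class` (named character)
#' @export
concept_lexicon <- function(terms = character(), cuis = character(), classes = NULL) {
  stopifnot(length(terms) == length(cuis))
  if (is.null(classes)) classes <- rep(NA_character_, length(terms))
  stopifnot(length(classes) == length(terms))
  norm <- normalize_term(terms)
  keep <- nzchar(norm)
  norm <- norm[keep]; cuis <- cuis[keep]; classes <- classes[keep]
  if (!length(norm)) {
    return(structure(list(term_to_cui = stats::setNames(character(), character()),
                          cui_to_terms = list(), cui_to_class = character()),
                     class = "ConceptLexicon"))
  }
  stopifnot(all(nzchar(cuis)))
  dup <- !duplicated(paste(norm, cuis, sep = "\r"))
  norm <- norm[dup]; cuis <- cuis[dup]; classes <- classes[dup]
  conflicts <- unique(norm[duplicated(norm)])
  if (length(conflicts)) {
    stop(sprintf("term(s) mapped to more than one CUI: %s",
                 paste(utils::head(conflicts, 5), collapse = ", ")), call. = FALSE)
  }
  term_to_cui <- stats::setNames(cuis, norm)
  cui_to_terms <- split(norm, cuis)
  cls_rows <- !is.na(classes)
  cui_to_class <- character()
  if (any(cls_rows)) {
    cls_by_cui <- tapply(classes[cls_rows], cuis[cls_rows], function(v) unique(v))
    bad <- names(cls_by_cui)[vapply(cls_by_cui, length, integer(1)) > 1L]
    if (length(bad)) {
      stop(sprintf("CUI(s) assigned conflicting classes: %s",
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    cui_to_class <- vapply(cls_by_cui, `[`, character(1), 1L)
  }
  structure(list(term_to_cui = term_to_cui, cui_to_terms = cui_to_terms,
                 cui_to_class = cui_to_class),
            class = "ConceptLexicon")
}

#' @export
print.ConceptLexicon <- function(x, ...) {
  cat(sprintf("<ConceptLexicon: %d terms, %d concepts, %d classed concepts>\n",
              length(x$term_to_cui), length(x$cui_to_terms), length(x$cui_to_class)))
  invisible(x)
}

#' Load a concept lexicon from a TSV file
#'
#' Expected columns: `term<TAB>cui<TAB>class`, the third optional per row.
#' Lines starting with `#` are ignored. Terms are normalized on load with
#' [normalize_term()]; two rows resolving one normalized term to different
#' CUIs raise an error naming the term.
#'
#' @param path TSV file path
#' @return a `ConceptLexicon`
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop(sprintf("lexicon file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(concept_lexicon())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 2L)) {
    stop(sprintf("lexicon line %d has fewer than 2 tab-separated fields",
                 which(nf < 2L)[1]), call. = FALSE)
  }
  concept_lexicon(
    terms = vapply(parts, `[`, character(1), 1L),
    cuis = vapply(parts, `[`, character(1), 2L),
    classes = vapply(parts, function(p) if (length(p) >= 3L && nzchar(p[3L])) p[3L] else NA_character_,
                     character(1))
  )
}

#' Write a concept lexicon to TSV
#' @param lexicon a `ConceptLexicon`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lexicon <- function(lexicon, path) {
  terms <- names(lexicon$term_to_cui)
  cuis <- unname(lexicon$term_to_cui)
  cls <- lexicon$cui_to_class[cuis]
  cls[is.na(cls)] <- ""
  writeLines(paste(terms, cuis, cls, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Resolve a URI or surface form to a CUI
#'
#' URIs are reduced to their local name first; the result is normalized and
#' looked up. Returns `NA` on a miss, never errors. Vectorised.
#'
#' @param lexicon a `ConceptLexicon`
#' @param uri_or_term character vector of URIs or raw terms
#' @return character vector of CUIs, `NA` where unresolved
#' @export
cui_of <- function(lexicon, uri_or_term) {
  if (!length(uri_or_term)) return(character())
  key <- normalize_term(local_name(uri_or_term))
  out <- unname(lexicon$term_to_cui[key])
  out[!nzchar(key) | is.na(key)] <- NA_character_
  out
}

#' Entity class of a CUI
#' @param lexicon a `ConceptLexicon`
#' @param cui character vector of CUIs
#' @return class per CUI (`NA` if unknown)
#' @export
class_of_cui <- function(lexicon, cui) {
  out <- unname(lexicon$cui_to_class[cui])
  out[is.na(cui)] <- NA_character_
  out
}

#' Extend a predicate set with concept aliases
#'
#' Annotates each predicate URI with its CUI (if its local name resolves in
#' the lexicon) and groups predicates sharing a CUI into mutual alias sets,
#' widening predicate matching across vocabularies the way synonym expansion
#' over a metathesaurus does. A predicate with no lexicon hit forms a
#' singleton group with CUI `NA`.
#'
#' @param predicates character vector of predicate URIs
#' @param lexicon a `ConceptLexicon`
#' @return an object of class `PredicateAliasTable`: a data.table with
#'   columns `predicate`, `cui`, and a list-column `aliases` holding the
#'   predicate's full alias group (itself included)
#' @export
extend_predicates <- function(predicates, lexicon) {
  predicates <- unique(predicates)
  cuis <- cui_of(lexicon, predicates)
  dt <- data.table::data.table(predicate = predicates, cui = cuis)
  grp <- split(dt$predicate, dt$cui)   # drops NA-cui predicates
  aliases <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    aliases[[i]] <- if (is.na(dt$cui[i])) dt$predicate[i] else sort(grp[[dt$cui[i]]])
  }
  dt[, aliases := aliases]
  data.table::setindexv(dt, "predicate")
  data.table::setattr(dt, "class", c("PredicateAliasTable", class(dt)))
  dt[]
}

#' Alias group of a predicate
#' @param table a `PredicateAliasTable`
#' @param predicate single predicate URI
#' @return character vector of aliases (the predicate itself if unknown)
#' @export
alias_group <- function(table, predicate) {
  i <- which(table$predicate == predicate)
  if (!length(i)) return(predicate)
  table$aliases[[i[1]]]
}
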