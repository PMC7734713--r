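#' Reserved vocabulary URIs
#'
#' The store uses a small reserved vocabulary: `myprop:Label` attaches a
#' human-readable label to an entity, `myclass:Gene` / `myclass:Drug` /
#' `myclass:Disorder` are the three entity classes used with `rdf:type`, and
#' `kgtrio:sameConcept` marks two URIs resolved to the same concept by link
#' mining. These helpers return the absolute URIs so fixtures, generators and
#' queries all agree on them.
#'
#' @return A single URI string (`kg_class_uri` is vectorised over `class`).
#' @examples
#' kg_label_predicate()
#' kg_class_uri("drug")
#' @name reserved-vocabulary
NULL

KG_NS_MYPROP <- "http://example.org/myprop#"
KG_NS_MYCLASS <- "http://example.org/myclass#"
KG_NS_BRIDGE <- "http://example.org/kgtrio#"
KG_RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

KG_CLASSES <- c("gene", "drug", "disorder")

#' @rdname reserved-vocabulary
#' @export
kg_label_predicate <- function() paste0(KG_NS_MYPROP, "Label")

#' @rdname reserved-vocabulary
#' @param class entity class, one of `"gene"`, `"drug"`, `"disorder"`
#' @export
kg_class_uri <- function(class) {
  stopifnot(all(class %in% KG_CLASSES))
  # myclass local names are capitalised: myclass:Gene etc.
  paste0(KG_NS_MYCLASS, paste0(toupper(substr(class, 1, 1)), substr(class, 2, nchar(class))))
}

#' @rdname reserved-vocabulary
#' @export
kg_same_concept_predicate <- function() paste0(KG_NS_BRIDGE, "sameConcept")

#' @rdname reserved-vocabulary
#' @export
kg_rdf_type <- function() KG_RDF_TYPE

# inverse of kg_class_uri; NA for URIs outside the myclass vocabulary
class_from_uri <- function(uri) {
  cls <- rep(NA_character_, length(uri))
  for (k in KG_CLASSES) cls[uri == kg_class_uri(k)] <- k
  cls
}
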