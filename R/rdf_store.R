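#' @importFrom data.table data.table as.data.table rbindlist setindexv setattr copy := .N .SD
NULL

empty_triples <- function() {
  data.table::data.table(
    subject = character(), predicate = character(), object = character(),
    literal = logical(), source = character()
  )
}

#' Create a triple store
#'
#' A `TripleStore` holds subject-predicate-object assertions from one or more
#' named datasets. Every triple carries the identifier of the dataset that
#' asserted it, so downstream queries can report per-source provenance.
#' Exact `(subject, predicate, object)` duplicates *within* one source are
#' collapsed; the same assertion arriving from two different sources is kept
#' once per source. Insertion order is preserved.
#'
#' @param triples optional data.frame with columns `subject`, `predicate`,
#'   `object`, `literal` (logical, TRUE for literal objects) and `source`.
#' @param namespaces named list, dataset id -> character vector of URI
#'   prefixes observed in that dataset.
#' @return An object of class `TripleStore`.
#' @export
triple_store <- function(triples = NULL, namespaces = list()) {
  dt <- empty_triples()
  store <- structure(
    list(triples = dt, namespaces = namespaces, indexed = FALSE),
    class = "TripleStore"
  )
  if (!is.null(triples)) store <- add_triples(store, triples)
  store
}

#' Add triples to a store
#'
#' Appends assertions, collapsing exact duplicates already present from the
#' same source, and records newly observed URI namespaces per dataset.
#'
#' @param store a `TripleStore`
#' @param triples data.frame with columns `subject`, `predicate`, `object`,
#'   `literal`, `source` (missing `literal` defaults to FALSE)
#' @return The updated store.
#' @export
add_triples <- function(store, triples) {
  stopifnot(inherits(store, "TripleStore"))
  dt <- data.table::as.data.table(triples)
  if (!"literal" %in% names(dt)) dt[, literal := FALSE]
  dt <- dt[, c("subject", "predicate", "object", "literal", "source"), with = FALSE]
  if (nrow(dt)) {
    stopifnot(!anyNA(dt$subject), !anyNA(dt$predicate), !anyNA(dt$object),
              all(nzchar(dt$source)))
    combined <- data.table::rbindlist(list(store$triples, dt),
                                      use.names = TRUE, fill = TRUE)
    combined <- unique(combined, by = c("subject", "predicate", "object", "literal", "source"))
    store$triples <- combined
    store$indexed <- FALSE
    for (src in unique(dt$source)) {
      uris <- c(dt[dt$source == src]$subject, dt[dt$source == src]$predicate,
                dt[dt$source == src & !dt$literal]$object)
      ns <- setdiff(unique(namespace_of(uris)), "")
      store$namespaces[[src]] <- sort(unique(c(store$namespaces[[src]], ns)))
    }
  }
  if (is.null(store$namespaces)) store$namespaces <- list()
  store
}

#' @export
print.TripleStore <- function(x, ...) {
  cat(sprintf("<TripleStore: %d triples, %d dataset(s): %s>\n",
              nrow(x$triples), length(x$namespaces),
              paste(names(x$namespaces), collapse = ", ")))
  invisible(x)
}

#' Number of triples in a store
#' @param store a `TripleStore`
#' @return integer count
#' @export
n_triples <- function(store) nrow(store$triples)

#' Triples of a store as a data.table
#' @param store a `TripleStore`
#' @return copy of the triple table (columns subject, predicate, object,
#'   literal, source, plus any CUI annotation columns)
#' @export
kg_triples <- function(store) data.table::copy(store$triples)

# ---- namespace handling -----------------------------------------------------

#' Split a URI into namespace and local name
#'
#' The namespace is the prefix up to and including the last `#`, or failing
#' that the last `/`; the local name is the remainder. Concatenating the two
#' reconstructs the URI. A string with neither separator is all local name
#' with an empty namespace (this is also how literals behave).
#'
#' @param uri character vector of URIs (or literal lexical forms)
#' @return character vector of namespaces resp. local names
#' @examples
#' namespace_of("http://www4.wiwiss.fu-berlin.de/semdb/OBJECT_NAME#PARK7")
#' local_name("http://www4.wiwiss.fu-berlin.de/semdb/OBJECT_NAME#PARK7")
#' @export
namespace_of <- function(uri) {
  pos_hash <- regexpr("#[^#]*$", uri)
  pos_slash <- regexpr("/[^/]*$", uri)
  cut <- ifelse(pos_hash > 0, pos_hash, ifelse(pos_slash > 0, pos_slash, 0L))
  ifelse(cut > 0, substr(uri, 1L, cut), "")
}

#' @rdname namespace_of
#' @export
local_name <- function(uri) {
  ns <- namespace_of(uri)
  substr(uri, nchar(ns) + 1L, nchar(uri))
}

# ---- N-Triples --------------------------------------------------------------

unescape_nt <- function(x) {
  # handles \" \\ \n \r \t and \uXXXX
  out <- gsub("\\\\u([0-9a-fA-F]{4})", "\\\\U\\1", x)
  has_u <- grepl("\\\\U", out, fixed = FALSE)
  if (any(has_u)) {
    out[has_u] <- vapply(out[has_u], function(s) {
      m <- gregexpr("\\\\U[0-9a-fA-F]{4}", s)[[1]]
      if (m[1] > 0) {
        codes <- regmatches(s, gregexpr("\\\\U[0-9a-fA-F]{4}", s))[[1]]
        for (cd in unique(codes)) {
          ch <- intToUtf8(strtoi(substr(cd, 3, 6), 16L))
          s <- gsub(cd, ch, s, fixed = TRUE)
        }
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  out <- gsub("\\n", "\n", out, fixed = TRUE)
  out <- gsub("\\r", "\r", out, fixed = TRUE)
  out <- gsub("\\t", "\t", out, fixed = TRUE)
  out <- gsub('\\"', '"', out, fixed = TRUE)
  gsub("\\\\", "\\", out, fixed = TRUE)
}

escape_nt <- function(x) {
  out <- gsub("\\", "\\\\", x, fixed = TRUE)
  out <- gsub('"', '\\"', out, fixed = TRUE)
  out <- gsub("\n", "\\n", out, fixed = TRUE)
  out <- gsub("\r", "\\r", out, fixed = TRUE)
  gsub("\t", "\\t", out, fixed = TRUE)
}

NT_LITERAL_RE <- '"(?:[^"\\\\]|\\\\.)*"(?:@[A-Za-z][A-Za-z0-9-]*|\\^\\^<[^>]*>)?'

parse_ntriples <- function(lines, path = "<text>") {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(data.table::data.table(subject = character(), predicate = character(),
                                  object = character(), literal = logical()))
  }
  pat <- paste0("^\\s*<([^>]*)>\\s+<([^>]*)>\\s+(<[^>]*>|", NT_LITERAL_RE, ")\\s*\\.\\s*$")
  m <- regmatches(lines[idx], regexec(pat, lines[idx]))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop(sprintf("malformed N-Triples in %s at line %d: %s",
                 path, idx[which(bad)[1]], trimws(lines[idx[which(bad)[1]]])),
         call. = FALSE)
  }
  subj <- vapply(m, `[`, character(1), 2L)
  pred <- vapply(m, `[`, character(1), 3L)
  obj_raw <- vapply(m, `[`, character(1), 4L)
  is_lit <- startsWith(obj_raw, '"')
  obj <- character(length(obj_raw))
  obj[!is_lit] <- substr(obj_raw[!is_lit], 2L, nchar(obj_raw[!is_lit]) - 1L)
  if (any(is_lit)) {
    lex <- sub('^"((?:[^"\\\\]|\\\\.)*)".*$', "\\1", obj_raw[is_lit])
    obj[is_lit] <- unescape_nt(lex)
  }
  data.table::data.table(subject = subj, predicate = pred, object = obj, literal = is_lit)
}

# ---- Turtle (pragmatic subset) ----------------------------------------------
# Supports @prefix/@base declarations, IRIs, prefixed names, 'a', literals
# (with language tag or datatype), and ';' / ',' predicate/object lists.
# Blank nodes, collections and multi-line literals are not supported.

tokenize_turtle <- function(text, path = "<text>") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pats <- c(
    iri = "^<[^>]*>",
    literal = paste0("^", NT_LITERAL_RE),
    prefix_decl = "^@(prefix|base)\\b",
    pname = "^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.%|-]*|^:[A-Za-z0-9_.%|-]*",
    a = "^a\\b",
    punct = "^[.;,]"
  )
  tokens <- list()
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    repeat {
      s <- sub("^\\s+", "", s)
      if (!nchar(s) || startsWith(s, "#")) break
      matched <- FALSE
      for (ty in names(pats)) {
        m <- regexpr(pats[[ty]], s)
        if (m == 1L) {
          tok <- substr(s, 1L, attr(m, "match.length"))
          tokens[[length(tokens) + 1L]] <- list(type = ty, text = tok, line = ln)
          s <- substr(s, attr(m, "match.length") + 1L, nchar(s))
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        stop(sprintf("malformed Turtle in %s at line %d near: %s", path, ln, s),
             call. = FALSE)
      }
    }
  }
  tokens
}

parse_turtle <- function(text, path = "<text>") {
  toks <- tokenize_turtle(text, path)
  prefixes <- list()
  base <- ""
  out <- list()
  i <- 1L
  n <- length(toks)
  tk <- function(j) if (j <= n) toks[[j]] else NULL
  resolve <- function(tok) {
    if (tok$type == "iri") return(substr(tok$text, 2L, nchar(tok$text) - 1L))
    if (tok$type == "a") return(KG_RDF_TYPE)
    if (tok$type == "pname") {
      colon <- regexpr(":", tok$text, fixed = TRUE)
      pfx <- substr(tok$text, 1L, colon - 1L)
      loc <- substr(tok$text, colon + 1L, nchar(tok$text))
      if (is.null(prefixes[[paste0(pfx, ":")]])) {
        stop(sprintf("undeclared Turtle prefix '%s:' in %s at line %d", pfx, path, tok$line),
             call. = FALSE)
      }
      return(paste0(prefixes[[paste0(pfx, ":")]], loc))
    }
    stop(sprintf("unexpected token '%s' in %s at line %d", tok$text, path, tok$line),
         call. = FALSE)
  }
  while (i <= n) {
    t0 <- tk(i)
    if (t0$type == "prefix_decl") {
      if (t0$text == "@base") {
        stopifnot(tk(i + 1L)$type == "iri")
        base <- substr(tk(i + 1L)$text, 2L, nchar(tk(i + 1L)$text) - 1L)
        i <- i + 3L  # @base <iri> .
        next
      }
      pn <- tk(i + 1L); ir <- tk(i + 2L)
      if (is.null(pn) || is.null(ir) || pn$type != "pname" || ir$type != "iri") {
        stop(sprintf("malformed @prefix in %s at line %d", path, t0$line), call. = FALSE)
      }
      prefixes[[pn$text]] <- substr(ir$text, 2L, nchar(ir$text) - 1L)
      i <- i + 3L
      if (!is.null(tk(i)) && tk(i)$text == ".") i <- i + 1L
      next
    }
    # triple statement: subject (predicate objectlist (';' predicate objectlist)*) '.'
    subj <- resolve(t0)
    i <- i + 1L
    repeat {
      pt <- tk(i)
      if (is.null(pt)) stop(sprintf("unexpected end of Turtle input in %s", path), call. = FALSE)
      pred <- resolve(pt)
      i <- i + 1L
      repeat {
        ot <- tk(i)
        if (is.null(ot)) stop(sprintf("unexpected end of Turtle input in %s", path), call. = FALSE)
        if (ot$type == "literal") {
          lex <- sub('^"((?:[^"\\\\]|\\\\.)*)".*$', "\\1", ot$text)
          out[[length(out) + 1L]] <- list(subject = subj, predicate = pred,
                                          object = unescape_nt(lex), literal = TRUE)
        } else {
          out[[length(out) + 1L]] <- list(subject = subj, predicate = pred,
                                          object = resolve(ot), literal = FALSE)
        }
        i <- i + 1L
        nt <- tk(i)
        if (!is.null(nt) && nt$text == ",") { i <- i + 1L; next }
        break
      }
      nt <- tk(i)
      if (!is.null(nt) && nt$text == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (!is.null(tk(i)) && tk(i)$text == ".") break
        next
      }
      break
    }
    nt <- tk(i)
    if (is.null(nt) || nt$text != ".") {
      at <- if (is.null(nt)) "end of input" else sprintf("line %d", nt$line)
      stop(sprintf("expected '.' in %s at %s", path, at), call. = FALSE)
    }
    i <- i + 1L
  }
  if (!length(out)) {
    return(data.table::data.table(subject = character(), predicate = character(),
                                  object = character(), literal = logical()))
  }
  data.table::rbindlist(out)
}

# ---- load / save ------------------------------------------------------------

#' Load an RDF file into a triple store
#'
#' Reads an N-Triples or Turtle file and tags every triple with
#' `dataset_id` as its provenance source. Exact duplicate assertions within
#' the file are collapsed. Language tags and datatype annotations on literals
#' are dropped; the lexical form is kept.
#'
#' @param path file path
#' @param format `"ntriples"` or `"turtle"` (default guessed from the file
#'   extension: `.ttl` means Turtle, anything else N-Triples)
#' @param dataset_id non-empty identifier for the dataset, e.g. `"semmed"`
#' @return a `TripleStore`
#' @export
load_rdf <- function(path, format = NULL, dataset_id) {
  if (!file.exists(path)) stop(sprintf("cannot read RDF file: %s", path), call. = FALSE)
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L, nzchar(dataset_id))
  if (is.null(format)) {
    format <- if (grepl("\\.ttl$", path, ignore.case = TRUE)) "turtle" else "ntriples"
  }
  format <- match.arg(format, c("ntriples", "turtle"))
  dt <- if (format == "ntriples") {
    parse_ntriples(readLines(path, warn = FALSE, encoding = "UTF-8"), path)
  } else {
    parse_turtle(paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n"), path)
  }
  if (nrow(dt)) dt[, source := dataset_id]
  store <- triple_store(if (nrow(dt)) dt else NULL)
  if (!nrow(dt)) store$namespaces[[dataset_id]] <- character()
  store
}

#' Serialize a store as N-Triples
#'
#' One triple per line, terminated by `" ."`, in insertion order. Provenance
#' is not encoded in N-Triples; use one file per dataset to keep it.
#'
#' @param store a `TripleStore`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_ntriples <- function(store, path) {
  dt <- store$triples
  lines <- character()
  if (nrow(dt)) {
    obj <- ifelse(dt$literal, paste0('"', escape_nt(dt$object), '"'),
                  paste0("<", dt$object, ">"))
    lines <- paste0("<", dt$subject, "> <", dt$predicate, "> ", obj, " .")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- index ------------------------------------------------------------------

#' Build the predicate-subject-object compound index
#'
#' Registers a secondary index on (predicate, subject, object) so that
#' lookups by predicate, by (predicate, subject) and by the full key are
#' answered by binary search instead of a full scan. Insertion order of the
#' triple table is untouched. Idempotent.
#'
#' @param store a `TripleStore`
#' @return the store, with the index registered
#' @export
build_pso_index <- function(store) {
  stopifnot(inherits(store, "TripleStore"))
  data.table::setindexv(store$triples, c("predicate", "subject", "object"))
  data.table::setindexv(store$triples, c("predicate", "subject"))
  data.table::setindexv(store$triples, "predicate")
  store$indexed <- TRUE
  store
}

#' Look up triples through the PSO index
#'
#' Any of the three components may be omitted; omitted components match
#' everything. Matching is on URIs / literal lexical forms, not CUIs.
#'
#' @param store a `TripleStore`
#' @param predicate,subject,object optional character vectors to match
#' @return data.table of matching triples (possibly zero rows)
#' @export
lookup_triples <- function(store, predicate = NULL, subject = NULL, object = NULL) {
  dt <- store$triples
  # build the i-tables outside `[` so argument names never collide with columns
  if (!is.null(predicate)) {
    i_tab <- data.table::data.table(predicate = unique(predicate))
    dt <- dt[i_tab, on = "predicate", nomatch = NULL, allow.cartesian = TRUE]
  }
  if (!is.null(subject)) {
    i_tab <- data.table::data.table(subject = unique(subject))
    dt <- dt[i_tab, on = "subject", nomatch = NULL, allow.cartesian = TRUE]
  }
  if (!is.null(object)) {
    i_tab <- data.table::data.table(object = unique(object))
    dt <- dt[i_tab, on = "object", nomatch = NULL, allow.cartesian = TRUE]
  }
  dt
}

# ---- merge ------------------------------------------------------------------

#' Merge several triple stores
#'
#' Concatenates the inputs, keeping every triple's original source tag, and
#' unions the namespace registries. Dataset identifiers must be pairwise
#' distinct across the inputs.
#'
#' @param stores list of `TripleStore` objects (may be empty)
#' @return a merged `TripleStore`
#' @export
merge_stores <- function(stores) {
  stopifnot(is.list(stores), all(vapply(stores, inherits, logical(1), "TripleStore")))
  ids <- unlist(lapply(stores, function(s) names(s$namespaces)))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate dataset id(s) across stores: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  out <- triple_store()
  for (s in stores) {
    if (nrow(s$triples)) out <- add_triples(out, s$triples)
    for (src in names(s$namespaces)) {
      out$namespaces[[src]] <- sort(unique(c(out$namespaces[[src]], s$namespaces[[src]])))
    }
  }
  out
}

#' Read a dataset manifest
#'
#' A manifest is a YAML or JSON file with a top-level `datasets` list whose
#' entries have fields `dataset_id`, `path` and optional `format`
#' (`ntriples`/`turtle`). Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file path
#' @return list of dataset descriptors
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  man <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- man$datasets
  if (is.null(entries)) stop("manifest has no 'datasets' entry", call. = FALSE)
  base_dir <- dirname(normalizePath(path))
  lapply(entries, function(e) {
    stopifnot(!is.null(e$dataset_id), !is.null(e$path))
    p <- e$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
    list(dataset_id = e$dataset_id, path = p, format = e$format)
  })
}
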