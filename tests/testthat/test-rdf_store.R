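test_that("N-Triples loading handles empty files, duplicates and provenance", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(character(), f)
  expect_equal(n_triples(load_rdf(f, "ntriples", "empty")), 0)

  line <- paste0("<http://www4.wiwiss.fu-berlin.de/semdb/SUBJECT_NAME#PARK2> ",
                 "<http://www4.wiwiss.fu-berlin.de/semdb/PREDICATE#COEXISTS_WITH> ",
                 "<http://www4.wiwiss.fu-berlin.de/semdb/OBJECT_NAME#PARK7> .")
  writeLines(line, f)
  st <- load_rdf(f, "ntriples", "semdb")
  expect_equal(n_triples(st), 1)
  expect_equal(st$triples$source, "semdb")
  expect_equal(local_name(st$triples$object), "PARK7")

  # exact duplicate written twice collapses within one source
  writeLines(c(line, "# a comment", line), f)
  expect_equal(n_triples(load_rdf(f, "ntriples", "semdb")), 1)
})

test_that("malformed N-Triples report the offending line number", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(c("<http://a#s> <http://a#p> <http://a#o> .",
               "this is not a triple"), f)
  expect_error(load_rdf(f, "ntriples", "x"), "line 2")
  expect_error(load_rdf(file.path(tempdir(), "nope-missing.nt"), "ntriples", "x"),
               "cannot read")
})

test_that("literals round-trip through N-Triples with escapes intact", {
  st <- triple_store(data.frame(
    subject = "http://a#s", predicate = kg_label_predicate(),
    object = 'a "quoted" label\twith\ttabs', literal = TRUE, source = "d"
  ))
  f <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(st, f)
  st2 <- load_rdf(f, "ntriples", "d")
  expect_equal(st2$triples$object, st$triples$object)
  expect_true(st2$triples$literal)
})

test_that("serialization round trip preserves the (s, p, o) set on random stores", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40
    dt <- data.frame(subject = random_uris(n, seed), predicate = random_uris(n, seed + 100),
                     object = random_uris(n, seed + 200), literal = FALSE, source = "r")
    st <- triple_store(dt)
    f <- withr::local_tempfile(fileext = ".nt")
    write_ntriples(st, f)
    st2 <- load_rdf(f, "ntriples", "r")
    key <- function(s) sort(paste(s$triples$subject, s$triples$predicate, s$triples$object))
    expect_equal(key(st2), key(st))
  }
})

test_that("the Turtle subset parses prefixes, lists, literals and 'a'", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix ex: <http://ex.org/e#> .",
    "@prefix myp: <http://example.org/myprop#> .",
    "# entity block",
    "ex:G1 a <http://example.org/myclass#Gene> ;",
    '  myp:Label "Gene one" ;',
    "  ex:coexists_with ex:G2, ex:G3 .",
    '<http://ex.org/e#G2> myp:Label "Gene two" .'
  ), f)
  st <- load_rdf(f, "turtle", "ttl")
  expect_equal(n_triples(st), 5)
  expect_equal(nrow(lookup_triples(st, predicate = "http://ex.org/e#coexists_with")), 2)
  expect_equal(lookup_triples(st, predicate = kg_rdf_type())$object,
               "http://example.org/myclass#Gene")
  labs <- lookup_triples(st, predicate = kg_label_predicate())
  expect_setequal(labs$object, c("Gene one", "Gene two"))
  expect_true(all(labs$literal))
  expect_error(load_rdf({
    g <- withr::local_tempfile(fileext = ".ttl")
    writeLines("undeclared:oops a undeclared:Thing .", g)
    g
  }, "turtle", "bad"), "undeclared")
})

test_that("N-Triples output parses identically under an independent RDF parser", {
  # cross-check the serializer against python rdflib on a small store
  py <- Sys.which("python")
  kg <- generate_toy_kg(synth_config(seed = 3, n_triples_per_source = 10))
  f <- tempfile(fileext = ".nt")
  write_ntriples(kg$stores$semmed, f)
  out <- suppressWarnings(system2(py, c("-c", shQuote(sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='nt'); print(len(g))", f
  ))), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    fail(paste("rdflib cross-check failed:", paste(out, collapse = " ")))
  }
  expect_equal(as.integer(out[length(out)]), n_triples(kg$stores$semmed))
})

test_that("namespace splitting follows last-#-else-last-/ and reconstructs URIs", {
  u <- "http://www4.wiwiss.fu-berlin.de/semdb/OBJECT_NAME#PARK7"
  expect_equal(namespace_of(u), "http://www4.wiwiss.fu-berlin.de/semdb/OBJECT_NAME#")
  expect_equal(local_name(u), "PARK7")
  expect_equal(namespace_of("PARK7"), "")
  expect_equal(local_name("PARK7"), "PARK7")
  expect_equal(namespace_of("http://a.org/path/leaf"), "http://a.org/path/")
  # round trip on random URIs
  us <- random_uris(100, seed = 9)
  expect_equal(paste0(namespace_of(us), local_name(us)), us)
})

test_that("merge keeps provenance, unions namespaces and rejects duplicate ids", {
  expect_equal(n_triples(merge_stores(list())), 0)
  mk <- function(src, ns) triple_store(data.frame(
    subject = paste0(ns, "s", 1:3), predicate = paste0(ns, "p"),
    object = paste0(ns, "o", 1:3), literal = FALSE, source = src
  ))
  a <- mk("d1", "http://one.org/x#")
  b <- mk("d2", "http://two.org/x#")
  m <- merge_stores(list(a, b))
  expect_equal(n_triples(m), 6)
  expect_equal(sort(unique(m$triples$source)), c("d1", "d2"))
  expect_setequal(names(m$namespaces), c("d1", "d2"))
  expect_error(merge_stores(list(a, mk("d1", "http://three.org/y#"))), "duplicate dataset id")
  # four-store merge: count is the sum of per-store counts
  stores <- lapply(1:4, function(i) mk(paste0("s", i), sprintf("http://ns%d.org/e#", i)))
  expect_equal(n_triples(merge_stores(stores)), sum(vapply(stores, n_triples, numeric(1))))
})

test_that("the PSO index is complete, consistent with a linear scan, and idempotent", {
  expect_equal(nrow(build_pso_index(triple_store())$triples), 0)
  kg <- generate_toy_kg(synth_config(seed = 11, n_triples_per_source = 25))
  st <- merge_stores(unname(kg$stores))
  st <- build_pso_index(st)
  for (p in sample(unique(st$triples$predicate), 5)) {
    via_index <- lookup_triples(st, predicate = p)
    via_scan <- st$triples[st$triples$predicate == p]
    expect_equal(nrow(via_index), nrow(via_scan))
    expect_setequal(paste(via_index$subject, via_index$object),
                    paste(via_scan$subject, via_scan$object))
  }
  s <- st$triples$subject[7]; p <- st$triples$predicate[7]
  via_index <- lookup_triples(st, predicate = p, subject = s)
  via_scan <- st$triples[st$triples$predicate == p & st$triples$subject == s]
  expect_setequal(via_index$object, via_scan$object)
  st2 <- build_pso_index(st)
  expect_equal(st2$triples, st$triples)
})
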