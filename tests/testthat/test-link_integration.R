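test_that("CUI annotation matches per-term lookups and leaves content unchanged", {
  kg <- generate_toy_kg(synth_config(seed = 13, n_triples_per_source = 25))
  st <- merge_stores(unname(kg$stores))
  before <- st$triples[, c("subject", "predicate", "object", "literal", "source")]
  st <- annotate_cuis(st, kg$lexicon)
  expect_equal(st$triples[, c("subject", "predicate", "object", "literal", "source")],
               before)
  expect_equal(st$triples$subject_cui, cui_of(kg$lexicon, st$triples$subject))
  expect_equal(st$triples$predicate_cui, cui_of(kg$lexicon, st$triples$predicate))
  expect_equal(st$triples$object_cui, cui_of(kg$lexicon, st$triples$object))
  # literal labels that miss the lexicon get NA object CUIs
  lab <- st$triples[st$triples$predicate == kg_label_predicate()]
  expect_true(all(!is.na(lab$object_cui)))  # entity labels are lexicon terms here
  miss <- annotate_cuis(triple_store(data.frame(
    subject = "http://x#a", predicate = "http://x#p", object = "free text",
    literal = TRUE, source = "d"
  )), kg$lexicon)
  expect_true(is.na(miss$triples$object_cui))
})

test_that("two concept-equal triples in different namespaces form exactly one link", {
  fx <- make_planted_pair()
  links <- mine_links(list(fx$s1, fx$s2), fx$lexicon)
  expect_equal(n_links(links), 1)
  expect_equal(links$links$subject_cui, "C_G")
  expect_equal(links$links$predicate_cui, "C_T")
  expect_equal(links$links$object_cui, "C_D")
  # same triple twice in one namespace and source: no namespace difference, no link
  dup <- triple_store(data.frame(
    subject = rep("http://ns1.org/e#GeneA", 2),
    predicate = rep("http://ns1.org/p#treats_like", 2),
    object = rep("http://ns1.org/e#DisX", 2),
    literal = FALSE, source = c("ds1", "ds3")
  ))
  expect_equal(n_links(mine_links(list(dup, triple_store()), fx$lexicon)), 0)
  expect_error(mine_links(list(), fx$lexicon), "at least two")
})

test_that("mine_links is symmetric in store order and equals the brute-force oracle", {
  for (seed in c(2, 19, 77)) {
    kg <- generate_toy_kg(synth_config(seed = seed, n_triples_per_source = 12,
                                       p_dup = 0.5))
    ab <- mine_links(unname(kg$stores), kg$lexicon)
    ba <- mine_links(rev(unname(kg$stores)), kg$lexicon)
    expect_equal(ab$links, ba$links)
    expect_equal(ab$links, oracle_links(unname(kg$stores), kg$lexicon)$links)
  }
})

test_that("adding a triple never removes an existing link", {
  fx <- make_planted_pair()
  before <- mine_links(list(fx$s1, fx$s2), fx$lexicon)$links
  s2 <- add_triples(fx$s2, data.frame(
    subject = "http://ns2.org/e#genea", predicate = "http://ns2.org/p#unrelated",
    object = "http://ns2.org/e#disx", literal = FALSE, source = "ds2"
  ))
  after <- mine_links(list(fx$s1, s2), fx$lexicon)$links
  key <- function(dt) paste(dt$left_subject, dt$left_predicate, dt$right_subject)
  expect_true(all(key(before) %in% key(after)))
})

test_that("materializing links adds the sameConcept bridges plus one cross assertion", {
  fx <- make_planted_pair()
  merged <- merge_stores(list(fx$s1, fx$s2))
  links <- mine_links(list(merged), fx$lexicon)
  expect_equal(n_links(links), 1)
  n0 <- n_triples(merged)
  aug <- materialize_links(merged, links)
  expect_equal(n_triples(aug), n0 + 3)
  same <- lookup_triples(aug, predicate = kg_same_concept_predicate())
  expect_equal(nrow(same), 2)
  expect_true(all(aug$triples$source[(n0 + 1):(n0 + 3)] == "kgtrio"))
  # original triples untouched, and re-materializing adds nothing
  expect_equal(aug$triples[1:n0, c("subject", "predicate", "object", "source")],
               merged$triples[, c("subject", "predicate", "object", "source")])
  expect_equal(n_triples(materialize_links(aug, links)), n_triples(aug))
  # empty link set: store unchanged
  expect_equal(n_triples(materialize_links(merged, empty <- mine_links(
    list(triple_store(), triple_store()), fx$lexicon))), n0)
})

test_that("integrate runs the full pipeline and recovers planted links from disk", {
  dir <- withr::local_tempdir()
  kg <- generate_toy_kg(synth_config(seed = 31, n_triples_per_source = 20, p_dup = 0.6))
  write_toy_kg(kg, dir)
  res <- integrate_datasets(file.path(dir, "datasets.yaml"), file.path(dir, "cui.tsv"))
  expect_equal(res$links$links, kg$truth$planted_links$links)
  expect_equal(sum(res$link_counts$links), n_links(kg$truth$planted_links))
  # augmented store grew by at most 3 triples per link and kept originals
  merged_n <- sum(vapply(kg$stores, n_triples, numeric(1)))
  expect_gte(n_triples(res$store), merged_n)
  expect_lte(n_triples(res$store), merged_n + 3 * n_links(res$links))

  # four empty stores integrate to an empty augmented store
  dir2 <- withr::local_tempdir()
  kg0 <- generate_toy_kg(synth_config(n_genes = 0, n_drugs = 0, n_disorders = 0,
                                      n_triples_per_source = 0, seed = 1))
  write_toy_kg(kg0, dir2)
  res0 <- integrate_datasets(file.path(dir2, "datasets.yaml"), file.path(dir2, "cui.tsv"))
  expect_equal(n_links(res0$links), 0)
  expect_equal(n_triples(res0$store), 0)
})

test_that("stage failures are labelled with the failing stage", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(datasets = list(list(dataset_id = "a", path = "missing.nt"))),
                   file.path(dir, "m.yaml"))
  writeLines("t\tC1", file.path(dir, "lex.tsv"))
  expect_error(integrate_datasets(file.path(dir, "m.yaml"), file.path(dir, "lex.tsv")),
               "\\[load\\]")
  expect_error(integrate_datasets(file.path(dir, "nope.yaml"), file.path(dir, "lex.tsv")),
               "\\[manifest\\]")
})
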