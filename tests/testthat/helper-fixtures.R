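# Worked-example store: one gene (PARK2) asserted related to six other genes
# across three namespaced sources, with labels and rdf:type triples.
table4_rows <- function() {
  semdb <- "http://www4.wiwiss.fu-berlin.de/semdb/"
  pgkb <- "http://www4.wiwiss.fu-berlin.de/pharmgkb/"
  up <- "http://www4.wiwiss.fu-berlin.de/uniprot"
  data.frame(
    subject = c(rep(paste0(semdb, "SUBJECT_NAME#PARK2"), 4),
                paste0(pgkb, "Entity1_NAME#PARK2"),
                paste0(up, "#PARK2")),
    predicate = c(rep(paste0(semdb, "PREDICATE#COEXISTS_WITH"), 4),
                  paste0(pgkb, "ASSOCIATION#ASSOCIATED"),
                  paste0(up, "/EXTERNALLINK")),
    object = c(paste0(semdb, "OBJECT_NAME#", c("PARK7", "GCH1", "PACRGgene|PACRG", "FBXW8")),
               paste0(pgkb, "Entity2_NAME#PINK1"),
               paste0(up, "#NBR1")),
    source = c(rep("semdb", 4), "pharmgkb", "uniprot"),
    stringsAsFactors = FALSE
  )
}

make_park2_store <- function() {
  rows <- table4_rows()
  rows$literal <- FALSE
  uris <- c(rows$subject, rows$object)
  labs <- c(rep("PARK2", nrow(rows)),
            c("PARK7", "GCH1", "PACRG", "FBXW8", "PINK1", "NBR1"))
  # each entity's type/label triples belong to the source that mentions it
  extra <- data.frame(
    subject = rep(uris, 2),
    predicate = c(rep(kg_rdf_type(), length(uris)),
                  rep(kg_label_predicate(), length(uris))),
    object = c(rep(kg_class_uri("gene"), length(uris)), labs),
    literal = rep(c(FALSE, TRUE), each = length(uris)),
    source = rep(c(rows$source, rows$source), 2),
    stringsAsFactors = FALSE
  )
  build_pso_index(triple_store(rbind(rows, extra)))
}

# two-source store pair with one planted concept-equal assertion
make_planted_pair <- function() {
  lex <- concept_lexicon(
    terms = c("genea", "disx", "treats like", "treatsAlias"),
    cuis = c("C_G", "C_D", "C_T", "C_T"),
    classes = c("gene", "disorder", NA, NA)
  )
  s1 <- triple_store(data.frame(
    subject = "http://ns1.org/e#GeneA", predicate = "http://ns1.org/p#treats_like",
    object = "http://ns1.org/e#DisX", literal = FALSE, source = "ds1"
  ))
  s2 <- triple_store(data.frame(
    subject = "http://ns2.org/e#genea", predicate = "http://ns2.org/p#treatsAlias",
    object = "http://ns2.org/e#disx", literal = FALSE, source = "ds2"
  ))
  list(s1 = s1, s2 = s2, lexicon = lex)
}

random_uris <- function(n, seed = 1) {
  set.seed(seed)
  ns <- sample(c("http://a.org/x#", "http://b.org/path/", "http://c.org/deep/d#"),
               n, replace = TRUE)
  paste0(ns, replicate(n, paste(sample(c(LETTERS, letters, 0:9), 8, TRUE), collapse = "")))
}

seed_label_for <- function(class) {
  paste0(toupper(substr(class, 1, 1)), substr(class, 2, nchar(class)), " 1")
}
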