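test_that("ATC level similarity follows the per-level Jaccard", {
  expect_equal(atc_level_similarity("N02BA01", "N02BA01", 3), 1)
  expect_equal(atc_similarity("N02BA01", "N02BA01"), 1)
  # shared through level 4, split at substance level
  for (k in 1:4) expect_equal(atc_level_similarity("N02BA01", "N02BA51", k), 1)
  expect_equal(atc_level_similarity("N02BA01", "N02BA51", 5), 0)
  expect_equal(atc_similarity("N02BA01", "N02BA51"), 0.8)
  # disjoint at the anatomical level
  expect_equal(atc_similarity("N02BA01", "C03CA01"), 0)
  expect_error(atc_similarity(character(), "N02BA01"), "non-empty")
  expect_error(atc_level_prefixes("BAD", 1), "invalid ATC")
})

test_that("multi-code ATC similarity matches the brute-force set oracle", {
  codes <- generate_toy_atc(n_drugs = 12, n_families = 4, codes_per_drug = 3,
                            shared_level = 2, seed = 5)
  set.seed(6)
  for (rep in 1:50) {
    pair <- sample(names(codes), 2)
    a <- codes[[pair[1]]]; b <- codes[[pair[2]]]
    expect_identical(atc_similarity(a, b), oracle_atc(a, b))
  }
})

test_that("single-code drugs sharing through level k score at least k/5", {
  for (k in 1:5) {
    codes <- generate_toy_atc(n_drugs = 6, n_families = 1, codes_per_drug = 1,
                              shared_level = k, seed = k)
    for (a in 1:5) for (b in (a + 1):6) {
      expect_gte(atc_similarity(codes[[a]], codes[[b]]), k / 5)
    }
  }
})

test_that("ontology ancestor sets are self-inclusive and cycles rejected", {
  dag <- toy_dag()
  onto <- ontology(dag$terms, dag$edges)
  expect_setequal(onto$ancestors[["D"]], c("D", "A", "B", "R"))
  expect_setequal(onto$ancestors[["R"]], "R")
  for (t in dag$terms)
    expect_setequal(onto$ancestors[[t]], oracle_ancestors(t, dag$edges))
  expect_error(ontology(c("x", "y"), rbind(c("x", "y"), c("y", "x"))), "cycle")
})

test_that("OBO files round-trip through the reader", {
  dag <- toy_dag()
  onto <- ontology(dag$terms, dag$edges)
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(onto, f)
  back <- read_obo(f)
  expect_setequal(back$terms, onto$terms)
  for (t in onto$terms)
    expect_setequal(back$ancestors[[t]], onto$ancestors[[t]])
})

test_that("obsolete terms and comments are skipped by the OBO reader", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: T:1", "",
               "[Term]", "id: T:2", "is_a: T:1 ! root", "",
               "[Term]", "id: T:3", "is_a: T:1", "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), f)
  onto <- read_obo(f)
  expect_setequal(onto$terms, c("T:1", "T:2"))
  expect_setequal(onto$ancestors[["T:2"]], c("T:2", "T:1"))
})

dag_corpus <- function() {
  dag <- toy_dag()
  onto <- ontology(dag$terms, dag$edges)
  ann <- data.frame(
    entity = c("g1", "g1", "g2", "g3", "g3", "g4"),
    term = c("C", "D", "D", "E", "B", "C"))
  list(dag = dag, onto = onto, ann = ann,
       corpus = annotation_corpus(onto, ann))
}

test_that("annotation probabilities are monotone along the DAG and root IC is 0", {
  cc <- dag_corpus()
  expect_equal(unname(cc$corpus$p[["R"]]), 1)
  expect_equal(unname(cc$corpus$ic[["R"]]), 0)
  for (row in seq_len(nrow(cc$dag$edges))) {
    child <- cc$dag$edges[row, 1]; parent <- cc$dag$edges[row, 2]
    pc <- cc$corpus$p[child]; pp <- cc$corpus$p[parent]
    if (!is.na(pc) && !is.na(pp)) expect_gte(unname(pp), unname(pc))
  }
})

test_that("term similarity equals the hand-enumerated IC-ratio oracle", {
  cc <- dag_corpus()
  # independent recomputation of P from the annotation table
  ents <- unique(cc$ann$entity)
  prop <- lapply(split(cc$ann$term, cc$ann$entity),
                 function(ts) unique(unlist(lapply(ts, oracle_ancestors,
                                                   edges = cc$dag$edges))))
  counts <- table(unlist(prop))
  ic <- -log(as.numeric(counts) / length(ents))
  names(ic) <- names(counts)

  annotated <- names(cc$corpus$p)
  for (c1 in annotated) for (c2 in annotated) {
    expect_equal(term_semantic_similarity(cc$corpus, c1, c2),
                 oracle_term_sim(c1, c2, cc$dag$edges, ic), tolerance = 1e-12)
  }
  expect_equal(term_semantic_similarity(cc$corpus, "C", "C"), 1)
  # the root carries zero information: no overlap signal
  expect_equal(term_semantic_similarity(cc$corpus, "R", "C"), 0)
  expect_error(term_semantic_similarity(cc$corpus, "C", "nope"), "unknown")
})

test_that("entity BMA similarity equals the exhaustive double-loop oracle", {
  cc <- dag_corpus()
  ts <- function(a, b) term_semantic_similarity(cc$corpus, a, b)
  ents <- names(cc$corpus$terms)
  for (e1 in ents) for (e2 in ents) {
    expect_equal(bma_similarity(cc$corpus, e1, e2),
                 oracle_bma(cc$corpus$terms[[e1]], cc$corpus$terms[[e2]], ts),
                 tolerance = 1e-12)
  }
  for (e in ents) expect_equal(bma_similarity(cc$corpus, e, e), 1)
  expect_equal(suppressMessages(bma_similarity(cc$corpus, "g1", "missing")), 0)
})

test_that("evidence-code and qualifier filters drop IEA / NOT annotations", {
  dag <- toy_dag()
  onto <- ontology(dag$terms, dag$edges)
  ann <- data.frame(entity = c("g1", "g1", "g2"),
                    term = c("C", "D", "C"),
                    evidence = c("EXP", "IEA", "EXP"),
                    qualifier = c("", "", "NOT|involved_in"))
  corpus <- annotation_corpus(onto, ann)
  expect_equal(corpus$terms[["g1"]], "C")
  expect_null(corpus$terms[["g2"]])
  corpus_all <- annotation_corpus(onto, ann, drop_iea = FALSE, drop_not = FALSE)
  expect_setequal(corpus_all$terms[["g1"]], c("C", "D"))
})

test_that("sub-ontology root whitelists restrict contributing terms", {
  dag <- toy_dag()
  onto <- ontology(dag$terms, dag$edges)
  expect_setequal(ontology_descendants(onto, "A"), c("A", "C", "D", "E"))
  ann <- data.frame(entity = c("g1", "g2"), term = c("C", "D"))
  corpus <- annotation_corpus(onto, ann, roots = "A")
  # B is an ancestor of D but lies outside the A subtree
  expect_false("B" %in% names(corpus$p))
  expect_true(all(names(corpus$p) %in% ontology_descendants(onto, "A")))
})

test_that("similarity matrix builders agree with element-wise kernel calls", {
  codes <- generate_toy_atc(n_drugs = 5, n_families = 2, codes_per_drug = 2,
                            shared_level = 3, seed = 2)
  idx <- entity_index(names(codes), "drug")
  m <- build_similarity_matrix(idx, codes)
  for (a in 1:4) for (b in (a + 1):5) {
    expect_equal(m[a, b], atc_similarity(codes[[a]], codes[[b]]))
    expect_equal(m[a, b], m[b, a])
  }
  expect_equal(unname(diag(unclass(m))), rep(1, 5))

  # identical code sets -> all-ones matrix
  same <- generate_toy_atc(n_drugs = 3, n_families = 1, codes_per_drug = 1,
                           shared_level = 5, seed = 3)
  m1 <- build_similarity_matrix(entity_index(names(same), "drug"), same)
  expect_equal(unclass(m1), matrix(1, 3, 3), ignore_attr = TRUE)

  cc <- dag_corpus()
  gidx <- entity_index(c(names(cc$corpus$terms), "g_none"), "gene")
  gm <- suppressMessages(build_similarity_matrix(gidx, cc$corpus))
  for (e1 in names(cc$corpus$terms)) for (e2 in names(cc$corpus$terms)) {
    expect_equal(gm[e1, e2], bma_similarity(cc$corpus, e1, e2), tolerance = 1e-12)
  }
  expect_equal(gm["g_none", "g_none"], 1)
  expect_equal(sum(gm["g_none", names(cc$corpus$terms)]), 0)
})

test_that("pair whitelists suppress similarities outside the listed pairs", {
  codes <- generate_toy_atc(n_drugs = 4, n_families = 1, codes_per_drug = 1,
                            shared_level = 5, seed = 4)
  idx <- entity_index(names(codes), "drug")
  wl <- data.frame(a = names(codes)[1], b = names(codes)[2])
  m <- build_similarity_matrix(idx, codes, pair_whitelist = wl)
  expect_equal(m[1, 2], 1)
  expect_equal(m[3, 4], 0)
  expect_equal(m[1, 3], 0)
})

test_that("sub-ontology combination averages where both corpora define a pair", {
  dag <- toy_dag()
  onto <- ontology(dag$terms, dag$edges)
  ann1 <- data.frame(entity = c("g1", "g2"), term = c("C", "D"))
  ann2 <- data.frame(entity = c("g1", "g3"), term = c("E", "E"))
  c1 <- annotation_corpus(onto, ann1)
  c2 <- annotation_corpus(onto, ann2)
  idx <- entity_index(c("g1", "g2", "g3"), "gene")
  m <- suppressMessages(combine_subontology_similarities(idx, list(c1, c2)))
  m1 <- suppressMessages(build_similarity_matrix(idx, c1))
  m2 <- suppressMessages(build_similarity_matrix(idx, c2))
  # g1-g2 only defined in corpus 1; g1-g3 only in corpus 2
  expect_equal(m["g1", "g2"], m1["g1", "g2"])
  expect_equal(m["g1", "g3"], m2["g1", "g3"])
  expect_equal(m["g2", "g3"], 0)
})

test_that("ATC and annotation tables round-trip through their readers", {
  codes <- generate_toy_atc(n_drugs = 4, n_families = 2, codes_per_drug = 2,
                            shared_level = 3, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_atc_table(codes, f)
  back <- read_atc_table(f)
  expect_equal(lapply(back, sort), lapply(codes[names(back)], sort),
               ignore_attr = TRUE)

  cc <- dag_corpus()
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(cc$ann, fa)
  corpus <- read_annotation_table(fa, cc$onto)
  expect_equal(corpus$p[names(cc$corpus$p)], cc$corpus$p)
})
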