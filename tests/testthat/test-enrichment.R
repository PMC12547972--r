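toy_dag <- function() {
  f <- file.path(tempdir(), "splithom-toy.obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leafA", "namespace: biological_process",
    "is_a: GO:0000002 ! mid", "",
    "[Term]", "id: GO:0000004", "name: leafB", "namespace: biological_process",
    "is_a: GO:0000002 ! mid",
    "relationship: part_of GO:0000001 ! root", "",
    "[Term]", "id: GO:0000005", "name: gone", "is_obsolete: true", ""
  ), f)
  read_obo(f)
}

test_that("OBO parsing collects terms and is_a/part_of edges, skipping obsolete terms", {
  dag <- toy_dag()
  expect_equal(sort(dag$terms$id), sprintf("GO:000000%d", 1:4))
  expect_true(all(c("is_a", "part_of") %in% dag$edges$rel))
  expect_setequal(term_ancestors(dag, "GO:0000003"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_setequal(term_descendants(dag, "GO:0000002"),
                  c("GO:0000002", "GO:0000003", "GO:0000004"))
})

test_that("annotation propagation closes over ancestors, idempotently, with set semantics", {
  dag <- toy_dag()
  ann <- tibble::tibble(protein_id = c("P1", "P2", "P2"),
                        term = c("GO:0000003", "GO:0000003", "GO:0000004"),
                        evidence = "IDA")
  closed <- propagate_annotations(dag, ann)
  expect_setequal(closed$term[closed$protein_id == "P1"],
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  # two children of one parent: the parent appears once per protein
  p2 <- dplyr::distinct(closed[closed$protein_id == "P2", c("protein_id", "term")])
  expect_equal(sum(p2$term == "GO:0000002"), 1)
  # idempotent
  again <- propagate_annotations(dag, closed)
  expect_setequal(paste(again$protein_id, again$term),
                  paste(closed$protein_id, closed$term))
  # unknown terms kept unpropagated with a warning
  expect_warning(
    kept <- propagate_annotations(
      dag, tibble::tibble(protein_id = "P3", term = "GO:9999999",
                          evidence = "IEA")),
    "absent")
  expect_equal(kept$term, "GO:9999999")
})

test_that("evidence-code subsets behave as documented", {
  ann <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P3"),
    term = "GO:0000003",
    evidence = c("IEA", "IDA", "IEA", "TAS")
  )
  expect_equal(filter_evidence(ann, "all"), ann)
  no_iea <- filter_evidence(ann, "noIEA")
  expect_false("P2" %in% no_iea$protein_id)   # IEA-only protein unannotated
  expect_true("P3" %in% no_iea$protein_id)
  exp_only <- filter_evidence(ann, "expOnly")
  expect_equal(exp_only$evidence, "IDA")
  expect_error(filter_evidence(ann, "bogus"))
})

test_that("Fisher term enrichment reproduces exact tables and BH adjustment", {
  dag <- toy_dag()
  # build proteins realizing the table [[3,1],[1,3]] for leafA:
  # study = S1..S4 (3 with the term), background adds B1..B4 (1 with it)
  ann <- tibble::tibble(
    protein_id = c("S1", "S2", "S3", "B1"),
    term = "GO:0000003", evidence = "IDA"
  )
  closed <- propagate_annotations(dag, ann)
  res <- fisher_term_enrichment(sprintf("S%d", 1:4), c(sprintf("S%d", 1:4),
                                                       sprintf("B%d", 1:4)),
                                closed)
  leaf <- res[res$term == "GO:0000003", ]
  expect_equal(leaf$study_count, 3L)
  expect_equal(leaf$bg_count, 4L)
  expect_equal(leaf$p, 34 / 70, tolerance = 1e-12)
  # BH is a monotone transform of the raw p-values
  expect_equal(order(res$p), order(res$p_adj))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_error(fisher_term_enrichment(character(), "B1", closed), "empty",
               class = "splithom_validation_error")
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  withr::local_seed(7006)
  for (i in 1:100) {
    tab <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    p_impl <- stats::fisher.test(matrix(tab, 2))$p.value
    expect_equal(p_impl, oracle_fisher_p(tab[1], tab[3], tab[2], tab[4]),
                 tolerance = 1e-9)
  }
  # symmetric table: p = 1, conditional-MLE odds ratio 1
  ft <- stats::fisher.test(matrix(c(1, 1, 1, 1), 2))
  expect_equal(ft$p.value, 1.0)
  expect_equal(unname(ft$estimate), 1.0)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  withr::local_seed(7007)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("mitochondrial flag uses the [Mm]itochondr regex", {
  cc <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4"),
    cc = c("Mitochondrion inner membrane", "Cytoplasm",
           "mitochondrial matrix", "Nucleus")
  )
  res <- mito_odds_ratio(c("P1", "P3"), c("P1", "P2", "P3", "P4"), cc)
  expect_equal(res$study_mito, 2L)
  expect_equal(res$bg_mito, 2L)
  expect_true(res$odds_ratio > 1 || is.infinite(res$odds_ratio))
})

test_that("GO-defined gene sets include descendants and honor excluded subtrees", {
  dag <- toy_dag()
  ann <- tibble::tibble(
    protein_id = c("P1", "P2", "P2", "P3"),
    term = c("GO:0000003", "GO:0000003", "GO:0000004", "GO:0000004"),
    evidence = "IDA"
  )
  closed <- propagate_annotations(dag, ann)
  # everything under mid; P2 and P3 disqualified via the leafB subtree
  expect_equal(build_go_gene_set(dag, closed, "GO:0000002",
                                 excluded_subtrees = "GO:0000004"),
               "P1")
  expect_equal(build_go_gene_set(dag, closed, "GO:0000002"),
               c("P1", "P2", "P3"))
  # plain set anchored at a leaf
  expect_equal(build_go_gene_set(dag, closed, "GO:0000004"), c("P2", "P3"))
  expect_error(build_go_gene_set(dag, closed, "GO:7777777"), "not in ontology",
               class = "splithom_validation_error")
  expect_setequal(unname(unlist(nucleobase_set_terms())),
                  c("GO:0006139", "GO:0006637", "GO:0015936", "GO:0046444",
                    "GO:0046443", "GO:0019362"))
})
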