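#' Read a Gene Ontology graph from an OBO file
#'
#' Minimal reader for `[Term]` stanzas: collects `id`, `name`, `namespace`,
#' and child-to-parent edges from `is_a` and `relationship: part_of` lines.
#' Obsolete terms are skipped.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology_dag`: list with `terms` (tibble
#'   `id`, `name`, `namespace`) and `edges` (tibble `child`, `parent`,
#'   `rel`), plus the igraph used for closure queries.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) {
    abort(sprintf("no [Term] stanzas found in '%s'", path),
          class = "splithom_io_error")
  }
  stanza_ends <- c(stanza_starts[-1] - 1, length(lines))
  recs <- purrr::map2(stanza_starts, stanza_ends, function(a, b) {
    chunk <- lines[a:b]
    field <- function(key) {
      v <- chunk[stringr::str_starts(chunk, paste0(key, ": "))]
      sub("!.*$", "", sub(paste0("^", key, ": "), "", v)) |>
        stringr::str_trim()
    }
    if (any(field("is_obsolete") == "true")) return(NULL)
    id <- field("id")[1]
    if (is.na(id)) return(NULL)
    isa <- field("is_a")
    rel <- field("relationship")
    partof <- sub("^part_of\\s+", "", rel[stringr::str_starts(rel, "part_of ")])
    list(
      term = tibble(id = id,
                    name = field("name")[1] %||% NA_character_,
                    namespace = field("namespace")[1] %||% NA_character_),
      edges = bind_rows(
        if (length(isa)) tibble(child = id, parent = isa, rel = "is_a"),
        if (length(partof)) tibble(child = id, parent = partof, rel = "part_of")
      )
    )
  })
  recs <- purrr::compact(recs)
  terms <- purrr::map_dfr(recs, "term")
  edges <- purrr::map_dfr(recs, "edges")
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms$id)
  )
  if (!igraph::is_dag(g)) {
    abort("ontology graph contains a cycle", class = "splithom_io_error")
  }
  structure(list(terms = terms, edges = edges, graph = g),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

dag_closure <- function(dag, terms, mode) {
  known <- intersect(terms, dag$terms$id)
  unique(unlist(lapply(known, function(t) {
    names(igraph::subcomponent(dag$graph, t, mode = mode))
  })))
}

#' All ancestors (inclusive) of a set of terms
#' @param dag An `ontology_dag`.
#' @param terms Character vector of term ids.
#' @return Character vector including `terms` and every ancestor.
#' @export
term_ancestors <- function(dag, terms) dag_closure(dag, terms, "out")

#' All descendants (inclusive) of a set of terms
#' @inheritParams term_ancestors
#' @return Character vector including `terms` and every descendant.
#' @export
term_descendants <- function(dag, terms) dag_closure(dag, terms, "in")

#' Propagate annotations up the ontology
#'
#' Annotates each protein to every ancestor of each of its terms (the
#' transitive closure over `is_a`/`part_of`), keeping the evidence code of
#' the source annotation. Idempotent. Annotations to terms absent from the
#' DAG are kept unpropagated with a warning.
#'
#' @param dag An `ontology_dag`.
#' @param annotations Tibble `protein_id`, `term`, `evidence` (extra columns
#'   are dropped).
#' @return Closed annotation tibble `protein_id`, `term`, `evidence`,
#'   `namespace`, distinct rows.
#' @export
propagate_annotations <- function(dag, annotations) {
  ann <- distinct(annotations[, c("protein_id", "term", "evidence")])
  unknown <- setdiff(unique(ann$term), dag$terms$id)
  if (length(unknown) > 0) {
    warn(sprintf("%d annotated term(s) absent from the ontology kept unpropagated",
                 length(unknown)))
  }
  anc_map <- lapply(setNames(nm = unique(ann$term)), function(t) {
    if (t %in% unknown) t else term_ancestors(dag, t)
  })
  closed <- ann %>%
    mutate(term = unname(anc_map[.data$term])) %>%
    tidyr::unnest_longer("term") %>%
    distinct()
  left_join(closed, select(dag$terms, term = "id", "namespace"), by = "term")
}

#' Subset annotations by GO evidence code
#'
#' `"all"` keeps everything, `"noIEA"` drops electronically inferred (IEA)
#' annotations, and `"expOnly"` keeps only direct experimental codes
#' (EXP, IDA, IPI, IMP, IGI, IEP).
#'
#' @param annotations Annotation tibble with an `evidence` column.
#' @param mode One of `"all"`, `"noIEA"`, `"expOnly"`.
#' @return Filtered annotation tibble.
#' @export
filter_evidence <- function(annotations, mode = c("all", "noIEA", "expOnly")) {
  mode <- match.arg(mode)
  switch(mode,
    all = annotations,
    noIEA = filter(annotations, .data$evidence != "IEA"),
    expOnly = filter(annotations,
                     .data$evidence %in% c("EXP", "IDA", "IPI", "IMP",
                                           "IGI", "IEP"))
  )
}

#' Fisher's exact GO term enrichment
#'
#' For every biological-process term with at least one study annotation,
#' tests the 2x2 table (in study vs not) x (annotated to term vs not) with a
#' two-sided Fisher's exact test (conditional-MLE odds ratio), then adjusts
#' p-values across the tested terms with Benjamini-Hochberg.
#'
#' @param study_set Character vector of protein ids (subset of background).
#' @param background_set Character vector of protein ids.
#' @param closed_annotations Propagated annotation tibble (see
#'   [propagate_annotations()]); only rows with `namespace` equal to
#'   `namespace` (default `biological_process`, `NA` namespaces kept out)
#'   are tested.
#' @param namespace Ontology namespace to test within.
#' @return Tibble `term`, `study_count`, `bg_count`, `odds_ratio`, `p`,
#'   `p_adj`, sorted by `p`.
#' @export
fisher_term_enrichment <- function(study_set, background_set,
                                   closed_annotations,
                                   namespace = "biological_process") {
  study_set <- unique(study_set)
  background_set <- unique(background_set)
  if (length(study_set) == 0) {
    abort("study set is empty", class = "splithom_validation_error")
  }
  if (!all(study_set %in% background_set)) {
    abort("study set must be a subset of the background set",
          class = "splithom_validation_error")
  }
  ann <- closed_annotations %>%
    filter(.data$namespace %in% !!namespace,
           .data$protein_id %in% background_set) %>%
    distinct(.data$protein_id, .data$term)
  terms <- ann %>%
    filter(.data$protein_id %in% study_set) %>%
    distinct(.data$term) %>%
    pull("term")
  if (length(terms) == 0) {
    return(tibble(term = character(), study_count = integer(),
                  bg_count = integer(), odds_ratio = numeric(),
                  p = numeric(), p_adj = numeric()))
  }
  n_study <- length(study_set)
  n_bg <- length(background_set)
  rows <- purrr::map_dfr(terms, function(t) {
    with_term <- ann$protein_id[ann$term == t]
    a <- sum(with_term %in% study_set)
    c_ <- length(with_term) - a
    ft <- fisher.test(matrix(c(a, n_study - a,
                               c_, (n_bg - n_study) - c_), nrow = 2))
    tibble(term = t, study_count = a, bg_count = length(with_term),
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  rows %>%
    mutate(p_adj = p.adjust(.data$p, method = "BH")) %>%
    arrange(.data$p, .data$term)
}

#' Mitochondrial localization odds ratio
#'
#' Flags a protein mitochondrial when any of its cellular-component strings
#' matches `[Mm]itochondr`, then tests flag-by-study-membership with a
#' two-sided Fisher's exact test.
#'
#' @param study_set,background_set Protein id vectors (study within
#'   background).
#' @param cc Tibble `protein_id`, `cc` of cellular-component strings.
#' @return Tibble with `odds_ratio`, `ci_low`, `ci_high`, `p`,
#'   `study_mito`, `bg_mito`.
#' @export
mito_odds_ratio <- function(study_set, background_set, cc) {
  study_set <- unique(study_set)
  background_set <- unique(background_set)
  mito_ids <- cc %>%
    filter(stringr::str_detect(.data$cc, "[Mm]itochondr")) %>%
    pull("protein_id") %>%
    unique()
  flag <- background_set %in% mito_ids
  in_study <- background_set %in% study_set
  ft <- fisher.test(table(factor(in_study, c(TRUE, FALSE)),
                          factor(flag, c(TRUE, FALSE))))
  tibble(odds_ratio = unname(ft$estimate),
         ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
         p = ft$p.value,
         study_mito = sum(flag & in_study), bg_mito = sum(flag))
}

#' Build a GO-defined protein set with excluded subtrees
#'
#' Proteins annotated (after propagation) to `root_term` or any of its
#' descendants, minus proteins annotated to any term in `excluded_subtrees`
#' or their descendants. With propagated annotations this reduces to
#' membership tests on the closed sets.
#'
#' @param dag An `ontology_dag`.
#' @param closed_annotations Propagated annotation tibble.
#' @param root_term GO id anchoring the set.
#' @param excluded_subtrees Character vector of GO ids whose subtrees
#'   disqualify a protein (default none).
#' @return Character vector of protein ids.
#' @export
build_go_gene_set <- function(dag, closed_annotations, root_term,
                              excluded_subtrees = character()) {
  if (!root_term %in% dag$terms$id) {
    abort(sprintf("root term '%s' not in ontology", root_term),
          class = "splithom_validation_error")
  }
  included <- closed_annotations %>%
    filter(.data$term == root_term) %>%
    pull("protein_id") %>%
    unique()
  if (length(excluded_subtrees) > 0) {
    excluded <- closed_annotations %>%
      filter(.data$term %in% excluded_subtrees) %>%
      pull("protein_id") %>%
      unique()
    included <- setdiff(included, excluded)
  }
  sort(included)
}

#' GO term ids for the nucleobase-metabolism gene set
#'
#' The nucleobase-containing compound metabolic process root
#' (`GO:0006139`) and the five excluded subtrees whose members mostly use
#' nucleotides as carriers (acyl-CoA, coenzyme A, FMN, FAD, and pyridine
#' nucleotide metabolic processes).
#'
#' @return List with `root` and `excluded`.
#' @export
nucleobase_set_terms <- function() {
  list(root = "GO:0006139",
       excluded = c("GO:0006637", "GO:0015936", "GO:0046444",
                    "GO:0046443", "GO:0019362"))
}

#' GO term id for the oxidoreductase gene set
#'
#' @return The oxidoreductase activity term id, `GO:0016491`.
#' @export
oxidoreductase_term <- function() "GO:0016491"
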