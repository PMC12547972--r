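#' Load a complete input bundle from a directory
#'
#' Expects the file layout written by [generate_fixture()]: `alignments.tsv`,
#' `gff/<genome>.gff3`, `cluster_map.tsv`, `taxonomy.tsv`, `host.faa`,
#' `tree.nwk`, `ontology.obo`, `annotations.tsv`, `protein_info.tsv`,
#' `reactions.tsv`, `chemicals.tsv`, `controller_map.tsv`, and optionally
#' `truth.tsv`.
#'
#' @param dir Bundle directory.
#' @return A list of parsed inputs (alignment tibble, features, cluster map,
#'   taxonomy, tree, ontology DAG, annotations, protein info, reaction
#'   tables, and `truth` when present).
#' @export
read_bundle <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      abort(sprintf("bundle file missing: %s", p), class = "splithom_io_error")
    }
    p
  }
  opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) p else NULL
  }
  truth_path <- opt("truth.tsv")
  list(
    dir = dir,
    hsps = read_alignments(need("alignments.tsv")),
    features = read_features_dir(need("gff")),
    cluster_map = read_cluster_map(need("cluster_map.tsv")),
    taxonomy = read_taxonomy(need("taxonomy.tsv")),
    tree = ape::read.tree(need("tree.nwk")),
    dag = read_obo(need("ontology.obo")),
    annotations = read_annotations(need("annotations.tsv")),
    protein_info = read_protein_info(need("protein_info.tsv")),
    reactions = read_tsv_flexible(need("reactions.tsv"),
                                  c("pathway_id", "reaction_type", "reactant",
                                    "product", "controller")),
    chemicals = read_tsv_flexible(need("chemicals.tsv"),
                                  c("chemical", "class")),
    controller_map = read_tsv_flexible(need("controller_map.tsv"),
                                       c("controller", "human_id")),
    truth = if (!is.null(truth_path)) {
      read_tsv_flexible(truth_path, c("human_id", "genome_id",
                                      "expected_call", "reason"))
    }
  )
}

#' Run the homolog-detection pipeline end to end
#'
#' Applies the shared filters (best host hit, microbe-side coverage and
#' length), the full-length branch (host coverage, contamination cutoff,
#' best call per genome), the split branch (genome expansion, joint
#' coverage, neighborhood adjacency, contamination re-check), and tallies
#' the results per host protein. Downstream summaries (class assignment,
#' presence matrices, PD ranking, enrichment, drug cross-reference) are run
#' when the bundle provides their inputs.
#'
#' @param bundle List from [read_bundle()] (or an equivalent in-memory
#'   bundle with at least `hsps`, `features`, `cluster_map`).
#' @param params [pipeline_params()].
#' @param unit Counting unit for tallies (see [tally_homologs()]).
#' @param evidence_mode Evidence-code subset for enrichment (see
#'   [filter_evidence()]).
#' @return An object of class `homology_run`: list with `params`, `model`,
#'   `full_calls`, `split_calls`, `tallies`, `ledger` (per-stage row
#'   counts), `recovery` (if planted truth is available), `class_pd`,
#'   `presence`, `enrichment`, `mito`, `drug_xref` (when inputs permit).
#' @export
run_pipeline <- function(bundle, params = pipeline_params(),
                         unit = "genome", evidence_mode = "all") {
  core <- run_homology_calls(bundle$hsps, bundle$cluster_map,
                             bundle$features, params)
  res <- list(params = params, model = core$model,
              full_calls = core$full_calls, split_calls = core$split_calls,
              tallies = tally_homologs(core$full_calls, core$split_calls,
                                       unit = if (unit == "species") "species" else unit,
                                       taxonomy = bundle$taxonomy),
              ledger = core$ledger)

  if (!is.null(bundle$truth)) {
    res$recovery <- score_recovery(core$full_calls, core$split_calls,
                                   bundle$truth)
  }

  if (!is.null(bundle$protein_info)) {
    classes <- bundle$protein_info %>%
      transmute_class_assignments()
    res$class_assignments <- classes
    if (!is.null(bundle$taxonomy)) {
      res$presence <- presence_matrix(core$full_calls, bundle$taxonomy,
                                      classes)
      if (!is.null(bundle$tree)) {
        rooted <- midpoint_root(bundle$tree)
        class_species <- core$full_calls %>%
          inner_join(filter(classes, !is.na(.data$class_key)),
                     by = "human_id") %>%
          inner_join(select(bundle$taxonomy, "genome_id", "species_id"),
                     by = "genome_id") %>%
          group_by(.data$class_key) %>%
          summarise(sp = list(unique(.data$species_id)), .groups = "drop")
        res$class_pd <- rank_classes_by_pd(
          setNames(class_species$sp, class_species$class_key), rooted)
      }
    }
    if (!is.null(bundle$dag) && !is.null(bundle$annotations)) {
      closed <- propagate_annotations(
        bundle$dag, filter_evidence(bundle$annotations, evidence_mode))
      background <- unique(bundle$protein_info$protein_id)
      study_full <- res$tallies %>%
        filter(.data$category == "full_dominant") %>%
        pull("human_id") %>%
        intersect(background)
      if (length(study_full) > 0) {
        res$enrichment <- fisher_term_enrichment(study_full, background,
                                                 closed)
        res$mito <- mito_odds_ratio(
          study_full, background,
          select(bundle$protein_info, "protein_id", "cc"))
      }
    }
  }

  if (!is.null(bundle$reactions) && !is.null(bundle$controller_map)) {
    rx <- filter_reactions(bundle$reactions, bundle$chemicals)
    res$drug_xref <- xref_drug_enzymes(rx, res$tallies,
                                       bundle$controller_map)
  }

  structure(res, class = "homology_run")
}

transmute_class_assignments <- function(protein_info) {
  tibble(human_id = protein_info$protein_id,
         class_key = assign_xenobiotic_class(protein_info$description))
}

#' @export
print.homology_run <- function(x, ...) {
  cat("Homolog detection run\n")
  cat(sprintf("  contamination cutoff: %.1f%% (mean %.1f, SD %.1f, n %d)\n",
              x$model$cutoff, x$model$mean_pident, x$model$sd_pident,
              x$model$n_alignments))
  cat(sprintf("  full-length calls: %d (%d host proteins)\n",
              nrow(x$full_calls), n_distinct(x$full_calls$human_id)))
  cat(sprintf("  split neighborhoods: %d (%d host proteins)\n",
              n_distinct(x$split_calls$neighborhood_id),
              n_distinct(x$split_calls$human_id)))
  if (!is.null(x$recovery)) {
    cat("  planted recovery:\n")
    for (i in seq_len(nrow(x$recovery))) {
      cat(sprintf("    %-5s precision %.3f recall %.3f\n",
                  x$recovery$type[i], x$recovery$precision[i],
                  x$recovery$recall[i]))
    }
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `homology_run`.
#' @param ... Unused.
#' @export
tidy.homology_run <- function(x, ...) x$tallies

#' @rdname run_pipeline
#' @export
glance.homology_run <- function(x, ...) {
  tibble(
    n_full_calls = nrow(x$full_calls),
    n_split_neighborhoods = n_distinct(x$split_calls$neighborhood_id),
    n_proteins_full = n_distinct(x$full_calls$human_id),
    n_proteins_split = n_distinct(x$split_calls$human_id),
    contamination_cutoff = x$model$cutoff
  )
}

#' Write pipeline outputs as TSVs plus a JSON manifest
#'
#' Emits `full_length_calls.tsv`, `split_calls.tsv`, `tallies.tsv`, and,
#' when computed, `class_assignments.tsv`, `presence_species.tsv`,
#' `presence_families.tsv`, `pd_per_class.tsv`, `enrichment.tsv`,
#' `drug_xref.tsv`, `recovery.tsv`, along with `manifest.json` recording
#' the parameters, input checksums, and the per-stage row-count ledger.
#'
#' @param run A `homology_run`.
#' @param out_dir Output directory (created if needed).
#' @param bundle Optional bundle used for input checksums in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir, bundle = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
    }
  }
  w(run$full_calls, "full_length_calls.tsv")
  w(run$split_calls, "split_calls.tsv")
  w(run$tallies, "tallies.tsv")
  w(run$class_assignments, "class_assignments.tsv")
  w(run$presence$species, "presence_species.tsv")
  w(run$presence$families, "presence_families.tsv")
  w(run$class_pd, "pd_per_class.tsv")
  w(run$enrichment, "enrichment.tsv")
  w(run$mito, "mito_odds_ratio.tsv")
  w(run$drug_xref, "drug_xref.tsv")
  w(run$recovery, "recovery.tsv")

  checksums <- NULL
  if (!is.null(bundle) && !is.null(bundle$dir) && dir.exists(bundle$dir)) {
    files <- sort(list.files(bundle$dir, recursive = TRUE, full.names = TRUE))
    checksums <- setNames(unname(tools::md5sum(files)),
                          sub(paste0("^", bundle$dir, "/?"), "", files))
  }
  manifest <- list(
    params = unclass(run$params),
    contamination = unclass(run$model)[c("mean_pident", "sd_pident",
                                         "cutoff", "n_alignments")],
    step_ledger = run$ledger,
    counts = as.list(glance(run)),
    input_checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
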