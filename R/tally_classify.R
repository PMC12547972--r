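#' Tally homologs per host protein
#'
#' `nFull` counts distinct genomes carrying a full-length call for the host
#' protein (optionally distinct microbial families or species instead, via
#' `unit`); `nSplit` counts distinct neighborhoods. A protein is
#' `split_dominant` when `nSplit > nFull`, `none` when both are zero, and
#' `full_dominant` otherwise.
#'
#' @param full_calls Tibble from [call_full_length()].
#' @param split_calls Tibble from [finalize_split_calls()].
#' @param unit Counting unit for `nFull`: `"genome"` (default), `"family"`,
#'   or `"species"` (requires `taxonomy`).
#' @param taxonomy Taxonomy tibble from [read_taxonomy()]; only needed for
#'   `unit = "species"`.
#' @return Tibble `human_id`, `nFull`, `nSplit`, `category`.
#' @export
tally_homologs <- function(full_calls, split_calls, unit = c("genome", "family", "species"),
                           taxonomy = NULL) {
  unit <- match.arg(unit)
  full_unit <- switch(unit,
    genome = full_calls %>% mutate(.unit = .data$genome_id),
    family = full_calls %>% mutate(.unit = .data$family_id),
    species = {
      if (is.null(taxonomy)) {
        abort("`taxonomy` is required for unit = \"species\"",
              class = "splithom_validation_error")
      }
      full_calls %>%
        inner_join(select(taxonomy, "genome_id", "species_id"),
                   by = "genome_id") %>%
        mutate(.unit = .data$species_id)
    }
  )
  nf <- full_unit %>%
    group_by(.data$human_id) %>%
    summarise(nFull = n_distinct(.data$.unit), .groups = "drop")
  ns <- split_calls %>%
    group_by(.data$human_id) %>%
    summarise(nSplit = n_distinct(.data$neighborhood_id), .groups = "drop")
  dplyr::full_join(nf, ns, by = "human_id") %>%
    mutate(nFull = dplyr::coalesce(.data$nFull, 0L),
           nSplit = dplyr::coalesce(.data$nSplit, 0L),
           category = case_when(
             .data$nFull == 0L & .data$nSplit == 0L ~ "none",
             .data$nSplit > .data$nFull ~ "split_dominant",
             TRUE ~ "full_dominant"
           )) %>%
    arrange(.data$human_id)
}

#' Run the coverage-threshold sensitivity grid
#'
#' Re-runs the full pipeline (contamination model refitted each time) for
#' every combination of microbe- and human-coverage levels — by default
#' microbe 50/67/75% crossed with human 60/70/80%, i.e. 9 parameter
#' combinations — and summarises, per host protein, in how many combinations
#' it is detected and in how many it keeps the same classification as under
#' the default thresholds.
#'
#' @param hsps Raw alignment tibble (before any filtering).
#' @param cluster_map,features As in [call_full_length()].
#' @param microbe_levels,human_levels Coverage levels to cross.
#' @param params Base [pipeline_params()] supplying the non-coverage
#'   thresholds and the default coverage pair used for the consensus
#'   reference.
#' @param unit Counting unit passed to [tally_homologs()].
#' @return An object of class `sensitivity_result`: list with `grid` (one
#'   tally row per protein per combination), `consensus` (per-protein
#'   `n_detected`, `n_same_as_default`), and the levels.
#' @export
sensitivity_grid <- function(hsps, cluster_map, features,
                             microbe_levels = c(0.50, 0.67, 0.75),
                             human_levels = c(0.60, 0.70, 0.80),
                             params = pipeline_params(),
                             unit = "genome") {
  stopifnot(length(microbe_levels) >= 1, length(human_levels) >= 1)
  combos <- tidyr::expand_grid(microbe_cov = microbe_levels,
                               human_cov = human_levels)
  grid <- purrr::pmap_dfr(combos, function(microbe_cov, human_cov) {
    p <- pipeline_params(
      microbe_cov_min = microbe_cov,
      human_cov_min = human_cov,
      min_microbe_len = params$min_microbe_len,
      contamination_sd_mult = params$contamination_sd_mult,
      max_feature_distance = params$max_feature_distance
    )
    run_homology_calls(hsps, cluster_map, features, p)$tallies %>%
      mutate(microbe_cov = microbe_cov, human_cov = human_cov,
             unit = unit, .before = 1)
  })

  ref <- run_homology_calls(hsps, cluster_map, features, params)$tallies %>%
    select("human_id", ref_category = "category")
  consensus <- grid %>%
    left_join(ref, by = "human_id") %>%
    mutate(ref_category = dplyr::coalesce(.data$ref_category, "none")) %>%
    group_by(.data$human_id) %>%
    summarise(
      n_detected = sum(.data$category != "none"),
      n_same_as_default = sum(.data$category == .data$ref_category),
      .groups = "drop"
    )
  structure(
    list(grid = grid, consensus = consensus,
         microbe_levels = microbe_levels, human_levels = human_levels,
         n_combinations = nrow(combos)),
    class = "sensitivity_result"
  )
}

# Shared single-run helper: steps 1-2, full-length branch, split branch.
run_homology_calls <- function(hsps, cluster_map, features, params) {
  s1 <- best_human_hit(hsps)
  s2 <- filter_microbe_side(s1, params)
  full <- call_full_length(s2, cluster_map, features, params)
  model <- attr(full, "contamination")
  split <- call_split(s2, cluster_map, features, model, params)
  tallies <- tally_homologs(full, split)
  ledger <- bind_rows(
    tibble(stage = c("input", "best_human_hit", "microbe_filter"),
           n = c(nrow(hsps), nrow(s1), nrow(s2))),
    tibble(stage = c("full_human_coverage", "full_contamination",
                     "full_calls"),
           n = c(sum(coverage_frac(s2, "subject") >= params$human_cov_min),
                 sum(coverage_frac(s2, "subject") >= params$human_cov_min &
                       s2$pident <= model$cutoff),
                 nrow(full))),
    attr(split, "ledger") %||% tibble(stage = character(), n = numeric())
  )
  list(step12 = s2, full_calls = full, split_calls = split, model = model,
       tallies = tallies, ledger = ledger, params = params)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity grid: %d microbe x %d human coverage levels = %d runs\n",
              length(x$microbe_levels), length(x$human_levels),
              x$n_combinations))
  cat(sprintf("%d host proteins detected in at least one combination\n",
              sum(x$consensus$n_detected > 0)))
  invisible(x)
}

#' @rdname sensitivity_grid
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @export
tidy.sensitivity_result <- function(x, ...) x$grid

#' @rdname sensitivity_grid
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble(n_combinations = x$n_combinations,
         n_proteins = nrow(x$consensus),
         n_detected_all = sum(x$consensus$n_detected == x$n_combinations))
}

#' Xenobiotic enzyme class definitions
#'
#' The ten host xenobiotic enzyme classes, each defined by a regular
#' expression over UniProt-style protein family description strings. Order
#' matters: the first matching class wins.
#'
#' @return Tibble with columns `class_key`, `regex`.
#' @export
xenobiotic_classes <- function() {
  tibble(
    class_key = c("akr", "udp", "gst", "aryl", "gdxg",
                  "cyto", "ester", "flavin", "sdr", "quin"),
    regex = c(
      "Aldo/keto reductase family",
      "UDP-glycosyltransferase family",
      "GST superfamily",
      "Arylamine N-acetyltransferase family",
      "'GDXG' lipolytic enzyme family",
      "Cytochrome P450 family",
      "Type-B carboxylesterase/lipase family",
      "Flavin monoamine oxidase family|FMO family",
      "Short-chain dehydrogenases/reductases \\(SDR\\)",
      "Quinone oxidoreductase subfamily"
    )
  )
}

#' Assign a xenobiotic class from a family description string
#'
#' @param description Character vector of protein family description strings.
#' @param class_table Tibble of class definitions; default
#'   [xenobiotic_classes()]. First match in table order wins.
#' @return Character vector of class keys, `NA` where no class matches.
#' @examples
#' assign_xenobiotic_class("Aldo/keto reductase family")   # "akr"
#' assign_xenobiotic_class("Histone deacetylase family")   # NA
#' @export
assign_xenobiotic_class <- function(description,
                                    class_table = xenobiotic_classes()) {
  hits <- vapply(description, function(d) {
    if (is.na(d)) return(NA_character_)
    m <- which(stringr::str_detect(d, class_table$regex))
    if (length(m) == 0) NA_character_ else class_table$class_key[m[1]]
  }, character(1), USE.NAMES = FALSE)
  hits
}

#' Species and protein-family presence matrices per xenobiotic class
#'
#' For full-length calls whose host protein falls in a xenobiotic class:
#' counts, per bacterial family (taxonomy rows) and class (columns), (a) the
#' number of distinct species with at least one call and (b) the number of
#' distinct microbial protein families detected.
#'
#' @param full_calls Tibble from [call_full_length()].
#' @param taxonomy Taxonomy tibble covering all genomes in the calls.
#' @param class_assignments Tibble `human_id`, `class_key` (NA rows ignored).
#' @return List with tibbles `species` and `families`, wide by class, plus
#'   `long` (bacterial_family, class_key, n_species, n_protein_families).
#' @export
presence_matrix <- function(full_calls, taxonomy, class_assignments) {
  classed <- full_calls %>%
    inner_join(dplyr::filter(class_assignments, !is.na(.data$class_key)),
               by = "human_id")
  missing <- setdiff(unique(classed$genome_id), taxonomy$genome_id)
  if (length(missing) > 0) {
    warn(sprintf("%d genome(s) missing from taxonomy excluded from presence matrix",
                 length(missing)))
  }
  long <- classed %>%
    inner_join(select(taxonomy, "genome_id", "species_id",
                      bacterial_family = "family"),
               by = "genome_id") %>%
    group_by(.data$bacterial_family, .data$class_key) %>%
    summarise(n_species = n_distinct(.data$species_id),
              n_protein_families = n_distinct(.data$family_id),
              .groups = "drop")
  widen <- function(col) {
    long %>%
      select("bacterial_family", "class_key", dplyr::all_of(col)) %>%
      tidyr::pivot_wider(names_from = "class_key",
                         values_from = dplyr::all_of(col),
                         values_fill = 0L) %>%
      arrange(.data$bacterial_family)
  }
  list(species = widen("n_species"), families = widen("n_protein_families"),
       long = long)
}
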