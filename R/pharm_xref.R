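#' Filter a pharmacogenomics reaction table to drug-relevant reactions
#'
#' Keeps reactions where the reactant and product differ, the reaction type
#' is not "Transport", the controller (enzyme) is known, and at least one of
#' reactant/product belongs to a chemical class of interest (by default
#' Drug, Drug Class, Prodrug, or Metabolite — excluding endogenous
#' "Biological Intermediate" chemicals).
#'
#' @param reactions Tibble with columns `pathway_id`, `reaction_type`,
#'   `reactant`, `product`, `controller`.
#' @param chemicals Tibble `chemical`, `class`.
#' @param interest_classes Chemical classes defining chemicals of interest.
#' @return Filtered reaction tibble with logical columns
#'   `reactant_of_interest`, `product_of_interest`.
#' @export
filter_reactions <- function(reactions, chemicals,
                             interest_classes = c("Drug", "Drug Class",
                                                  "Prodrug", "Metabolite")) {
  interest <- chemicals %>%
    filter(.data$class %in% interest_classes) %>%
    pull("chemical") %>%
    unique()
  reactions %>%
    filter(nzchar(.data$reactant), nzchar(.data$product)) %>%
    filter(.data$reactant != .data$product,
           .data$reaction_type != "Transport",
           !is.na(.data$controller) & nzchar(.data$controller) &
             tolower(.data$controller) != "unknown") %>%
    mutate(reactant_of_interest = .data$reactant %in% interest,
           product_of_interest = .data$product %in% interest) %>%
    filter(.data$reactant_of_interest | .data$product_of_interest)
}

#' Cross-reference drug-metabolizing enzymes with homolog tallies
#'
#' Maps reaction controllers to host protein ids, keeps controllers whose
#' homolog tally matches `category_filter` (e.g. proteins with more split
#' than full-length homologs), and aggregates the distinct chemicals of
#' interest each controller touches.
#'
#' @param reactions Filtered reaction tibble from [filter_reactions()].
#' @param tallies Tally tibble from [tally_homologs()].
#' @param controller_map Tibble `controller`, `human_id`.
#' @param category_filter Tally categories to keep (default
#'   `"split_dominant"`); `NULL` keeps every category except `"none"`.
#' @return Tibble `controller`, `human_id`, `nFull`, `nSplit`, `category`,
#'   `drugs` (comma-joined, sorted, distinct), `n_drugs`, ordered by
#'   descending `nSplit`.
#' @export
xref_drug_enzymes <- function(reactions, tallies, controller_map,
                              category_filter = "split_dominant") {
  unmapped <- setdiff(unique(reactions$controller), controller_map$controller)
  if (length(unmapped) > 0) {
    warn(sprintf("%d controller(s) without a host protein mapping excluded",
                 length(unmapped)))
  }
  mapped <- reactions %>%
    inner_join(controller_map, by = "controller")
  absent <- setdiff(unique(mapped$human_id), tallies$human_id)
  if (length(absent) > 0) {
    warn(sprintf("%d controller protein(s) absent from tallies excluded",
                 length(absent)))
    mapped <- filter(mapped, !.data$human_id %in% absent)
  }
  keep_cat <- category_filter %||% c("full_dominant", "split_dominant")
  mapped %>%
    tidyr::pivot_longer(c("reactant", "product"), names_to = "side",
                        values_to = "chemical") %>%
    filter((.data$side == "reactant" & .data$reactant_of_interest) |
             (.data$side == "product" & .data$product_of_interest)) %>%
    distinct(.data$controller, .data$human_id, .data$chemical) %>%
    inner_join(tallies, by = "human_id") %>%
    filter(.data$category %in% keep_cat) %>%
    group_by(.data$controller, .data$human_id, .data$nFull, .data$nSplit,
             .data$category) %>%
    summarise(drugs = paste(sort(unique(.data$chemical)), collapse = ", "),
              n_drugs = n_distinct(.data$chemical), .groups = "drop") %>%
    arrange(desc(.data$nSplit), .data$controller)
}
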