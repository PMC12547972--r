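#' Fraction of a protein covered by the union of aligned intervals
#'
#' Intervals are 1-based inclusive positions on the subject protein; the
#' union of positions is computed with `IRanges::reduce()`.
#'
#' @param start,end Integer vectors of interval bounds.
#' @param length Protein length in residues.
#' @return Fraction of positions covered, in \[0, 1\].
#' @examples
#' union_coverage(c(1, 50), c(60, 120), 150)  # 0.80
#' union_coverage(c(1, 80), c(60, 150), 150)  # 131/150
#' @export
union_coverage <- function(start, end, length) {
  if (length(start) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  sum(IRanges::width(ir)) / length
}

#' Expand family-level alignments to per-genome gene instances
#'
#' Each HSP is joined to every member gene of its family (cluster map) and
#' that gene's feature record, yielding one instance per (HSP, gene). For
#' split-homolog detection only genomes encoding at least two distinct
#' families aligned to a given host protein are informative, so
#' (host protein, genome) groups with fewer are dropped.
#'
#' @param hsps Alignment tibble after the shared filters.
#' @param cluster_map Tibble `gene_id` -> `family_id`.
#' @param features Feature tibble.
#' @return Instance tibble with columns `human_id`, `genome_id`, `contig_id`,
#'   `strand`, `feature_rank`, `gene_id`, `family_id`, `sstart`, `send`,
#'   `slen`, `pident`, `bitscore`, `evalue`, `scov`.
#' @export
expand_to_genomes <- function(hsps, cluster_map, features) {
  inst <- hsps %>%
    mutate(scov = coverage_frac(hsps, "subject")) %>%
    inner_join(cluster_map, by = c(qseqid = "family_id"), relationship = "many-to-many") %>%
    rename(family_id = "qseqid", human_id = "sseqid")
  missing <- anti_join(inst, features, by = "gene_id")
  if (nrow(missing) > 0) {
    warn(sprintf("%d instance(s) skipped: gene without feature record",
                 nrow(missing)))
  }
  inst %>%
    inner_join(select(features, "gene_id", "genome_id", "contig_id",
                      "strand", "feature_rank"),
               by = "gene_id") %>%
    group_by(.data$human_id, .data$genome_id) %>%
    filter(n_distinct(.data$family_id) >= 2) %>%
    ungroup() %>%
    select("human_id", "genome_id", "contig_id", "strand", "feature_rank",
           "gene_id", "family_id", "sstart", "send", "slen", "pident",
           "bitscore", "evalue", "scov")
}

#' Joint-but-not-individual coverage candidates
#'
#' Keeps (host protein, genome) groups whose alignments jointly cover at
#' least `human_cov_min` of the host protein while no single member reaches
#' that threshold on its own. Groups containing an individually qualifying
#' member are routed to the full-length pipeline and excluded here entirely.
#'
#' @param instances Instance tibble from [expand_to_genomes()].
#' @param params [pipeline_params()].
#' @return Filtered instance tibble.
#' @export
joint_candidates <- function(instances, params = pipeline_params()) {
  instances %>%
    group_by(.data$human_id, .data$genome_id) %>%
    filter(all(.data$scov < params$human_cov_min),
           union_coverage(.data$sstart, .data$send, .data$slen[1]) >=
             params$human_cov_min) %>%
    ungroup()
}

# Split sorted ranks into chained components: a new component starts wherever
# the gap to the previous rank exceeds max_gap.
chain_components <- function(ranks, max_gap) {
  ord <- order(ranks)
  comp <- integer(length(ranks))
  comp[ord] <- cumsum(c(1L, diff(ranks[ord]) > max_gap))
  comp
}

#' Neighborhood (feature-distance) filter
#'
#' Within each candidate (host protein, genome) group, instances are
#' partitioned by contig and strand and chained into connected components in
#' which consecutive feature ranks differ by at most `max_feature_distance`.
#' Components with at least two distinct families are kept, and joint host
#' coverage is recomputed and re-tested per component, since members may have
#' been removed.
#'
#' @param candidates Instance tibble from [joint_candidates()].
#' @param params [pipeline_params()].
#' @return Instance tibble with an added `neighborhood_id` column.
#' @export
neighborhood_filter <- function(candidates, params = pipeline_params()) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, neighborhood_id = character()))
  }
  candidates %>%
    group_by(.data$human_id, .data$genome_id, .data$contig_id, .data$strand) %>%
    mutate(.comp = chain_components(.data$feature_rank,
                                    params$max_feature_distance)) %>%
    group_by(.data$.comp, .add = TRUE) %>%
    filter(n_distinct(.data$family_id) >= 2,
           union_coverage(.data$sstart, .data$send, .data$slen[1]) >=
             params$human_cov_min) %>%
    mutate(neighborhood_id = paste(.data$human_id, .data$genome_id,
                                   .data$contig_id, .data$strand,
                                   .data$.comp, sep = "|")) %>%
    ungroup() %>%
    select(-".comp")
}

#' Final contamination filter and re-check for split calls
#'
#' Removes member instances whose percent identity exceeds the contamination
#' cutoff fitted on the full-length candidate set, then re-tests each
#' surviving neighborhood for at least two distinct families and joint host
#' coverage.
#'
#' @param neighborhoods Tibble from [neighborhood_filter()].
#' @param model `contamination_model` fitted by the full-length pipeline.
#' @param params [pipeline_params()].
#' @return Final split-call tibble, one row per (neighborhood, member), with
#'   a `joint_coverage` column.
#' @export
finalize_split_calls <- function(neighborhoods, model,
                                 params = pipeline_params()) {
  if (nrow(neighborhoods) == 0) {
    return(mutate(neighborhoods, joint_coverage = numeric()))
  }
  out <- neighborhoods %>%
    filter(.data$pident <= model$cutoff) %>%
    group_by(.data$neighborhood_id) %>%
    mutate(joint_coverage =
             union_coverage(.data$sstart, .data$send, .data$slen[1])) %>%
    filter(n_distinct(.data$family_id) >= 2,
           .data$joint_coverage[1] >= params$human_cov_min) %>%
    ungroup() %>%
    arrange(.data$human_id, .data$genome_id, .data$feature_rank)
  out
}

#' Run the whole split-homolog branch
#'
#' Convenience wrapper chaining [expand_to_genomes()], [joint_candidates()],
#' [neighborhood_filter()] and [finalize_split_calls()].
#'
#' @inheritParams expand_to_genomes
#' @inheritParams finalize_split_calls
#' @param params [pipeline_params()].
#' @return Final split-call tibble (see [finalize_split_calls()]), with the
#'   per-stage row counts attached as attribute `"ledger"`.
#' @export
call_split <- function(hsps, cluster_map, features, model,
                       params = pipeline_params()) {
  inst <- expand_to_genomes(hsps, cluster_map, features)
  cand <- joint_candidates(inst, params)
  nbh <- neighborhood_filter(cand, params)
  fin <- finalize_split_calls(nbh, model, params)
  attr(fin, "ledger") <- tibble(
    stage = c("split_instances", "split_joint_candidates",
              "split_neighborhoods", "split_final"),
    n = c(nrow(inst), nrow(cand), nrow(nbh), nrow(fin))
  )
  fin
}
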