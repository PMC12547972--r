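#' Alignment coverage of the query or subject protein
#'
#' Coverage is the aligned interval length over the protein length, with
#' 1-based inclusive coordinates: `(end - start + 1) / length`.
#'
#' @param hsps Alignment tibble.
#' @param side `"query"` (microbial family) or `"subject"` (host protein).
#' @return Numeric vector of coverage fractions in (0, 1].
#' @examples
#' hsp <- tibble::tibble(qstart = 1, qend = 100, qlen = 150,
#'                       sstart = 10, send = 39, slen = 100)
#' coverage_frac(hsp, "query")   # 100/150
#' coverage_frac(hsp, "subject") # 0.30
#' @export
coverage_frac <- function(hsps, side = c("query", "subject")) {
  side <- match.arg(side)
  if (side == "query") {
    (hsps$qend - hsps$qstart + 1) / hsps$qlen
  } else {
    (hsps$send - hsps$sstart + 1) / hsps$slen
  }
}

# bitscore desc, then e-value asc, then lexicographic accession: the fixed
# tie-break order used everywhere a single best row is kept.
arrange_best <- function(df, accession_col) {
  arrange(df, desc(.data$bitscore), .data$evalue, .data[[accession_col]])
}

#' Keep each microbial family's best host protein
#'
#' For every query family, the host protein of its maximum-bitscore HSP is
#' selected (ties broken by ascending e-value, then lexicographically smaller
#' host accession) and all HSPs pairing the family with that host protein are
#' retained; HSPs to other host proteins are dropped.
#'
#' @param hsps Alignment tibble.
#' @return Filtered alignment tibble.
#' @export
best_human_hit <- function(hsps) {
  if (nrow(hsps) == 0) return(hsps)
  best <- hsps %>%
    group_by(.data$qseqid) %>%
    arrange(desc(.data$bitscore), .data$evalue, .data$sseqid,
            .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select("qseqid", "sseqid")
  semi_join(hsps, best, by = c("qseqid", "sseqid"))
}

#' Microbe-side coverage and length filter
#'
#' Retains HSPs whose query coverage is at least `microbe_cov_min` and whose
#' microbial protein is at least `min_microbe_len` residues long.
#'
#' @param hsps Alignment tibble.
#' @param params [pipeline_params()].
#' @return Filtered alignment tibble.
#' @export
filter_microbe_side <- function(hsps, params = pipeline_params()) {
  hsps[coverage_frac(hsps, "query") >= params$microbe_cov_min &
         hsps$qlen >= params$min_microbe_len, , drop = FALSE]
}

#' Fit the contamination model on percent identity
#'
#' Models likely host contamination of microbial assemblies: alignments with
#' unusually high amino-acid identity are suspect. The model is the mean and
#' sample standard deviation (n - 1 denominator) of `pident` over the
#' alignments that survived the host-coverage filter, with cutoff
#' `mean + sd_mult * sd`. The same fitted cutoff is reused by the split
#' pipeline's final contamination step.
#'
#' @param hsps Alignment tibble (the host-coverage-filtered set).
#' @param sd_mult Multiplier on the standard deviation; default 3.
#' @return An object of class `contamination_model` with elements
#'   `mean_pident`, `sd_pident`, `cutoff`, `n_alignments`.
#' @examples
#' m <- fit_contamination(tibble::tibble(pident = c(20, 30, 40)))
#' m$cutoff # 60
#' @export
fit_contamination <- function(hsps, sd_mult = 3) {
  x <- hsps$pident
  if (length(x) < 2) {
    abort("insufficient alignments for contamination model (n < 2)",
          class = "splithom_validation_error")
  }
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    warn("contamination model is degenerate (SD = 0); cutoff equals the mean")
  }
  structure(
    list(mean_pident = m, sd_pident = s, cutoff = m + sd_mult * s,
         n_alignments = length(x)),
    class = "contamination_model"
  )
}

#' @export
print.contamination_model <- function(x, ...) {
  cat(sprintf(
    "Contamination model: mean %.1f%%, SD %.1f%%, cutoff %.1f%% (n = %d)\n",
    x$mean_pident, x$sd_pident, x$cutoff, x$n_alignments))
  invisible(x)
}

#' @rdname fit_contamination
#' @param x A `contamination_model`.
#' @param ... Unused.
#' @export
tidy.contamination_model <- function(x, ...) {
  tibble(mean_pident = x$mean_pident, sd_pident = x$sd_pident,
         cutoff = x$cutoff, n_alignments = x$n_alignments)
}

#' @rdname fit_contamination
#' @export
glance.contamination_model <- function(x, ...) tidy.contamination_model(x)

#' Call full-length homologs
#'
#' From alignments that already passed the best-host-hit and microbe-side
#' filters: (i) retain HSPs covering at least `human_cov_min` of the host
#' protein; (ii) fit (or reuse) the contamination model on that set and drop
#' HSPs with `pident` above the cutoff; (iii) expand families to their member
#' genes and genomes through the cluster map and feature tables; (iv) keep a
#' single best call per (host protein, genome) by bitscore, with the standard
#' tie-breaks.
#'
#' @param hsps Alignment tibble after the shared filters.
#' @param cluster_map Tibble `gene_id` -> `family_id`.
#' @param features Feature tibble from [read_features()].
#' @param params [pipeline_params()].
#' @param model Optional prefit `contamination_model`; fitted from the
#'   host-coverage-filtered HSPs when `NULL`.
#' @return Tibble of full-length calls (`human_id`, `genome_id`, `family_id`,
#'   `gene_id`, `human_coverage`, `microbe_coverage`, `pident`, `bitscore`),
#'   with the `contamination_model` attached as attribute `"contamination"`.
#' @export
call_full_length <- function(hsps, cluster_map, features,
                             params = pipeline_params(), model = NULL) {
  f3 <- hsps[coverage_frac(hsps, "subject") >= params$human_cov_min, ,
             drop = FALSE]
  if (is.null(model)) {
    model <- fit_contamination(f3, params$contamination_sd_mult)
  }
  f4 <- f3[f3$pident <= model$cutoff, , drop = FALSE]

  expanded <- f4 %>%
    mutate(human_coverage = coverage_frac(f4, "subject"),
           microbe_coverage = coverage_frac(f4, "query")) %>%
    inner_join(cluster_map, by = c(qseqid = "family_id"), relationship = "many-to-many") %>%
    rename(family_id = "qseqid", human_id = "sseqid") %>%
    inner_join(select(features, "gene_id", "genome_id"), by = "gene_id")

  orphans <- setdiff(unique(f4$qseqid), unique(expanded$family_id))
  if (length(orphans) > 0) {
    warn(sprintf("%d famil%s with no genome members excluded from full-length calls",
                 length(orphans), if (length(orphans) == 1) "y" else "ies"))
  }

  calls <- expanded %>%
    group_by(.data$human_id, .data$genome_id) %>%
    arrange(desc(.data$bitscore), .data$evalue, .data$gene_id,
            .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select("human_id", "genome_id", "family_id", "gene_id",
           "human_coverage", "microbe_coverage", "pident", "bitscore") %>%
    arrange(.data$human_id, .data$genome_id)
  attr(calls, "contamination") <- model
  calls
}
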