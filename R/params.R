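#' Pipeline filtering parameters
#'
#' Bundles the thresholds used throughout homolog detection. Defaults follow
#' the conventional ortholog-calling settings this pipeline is built around:
#' an alignment must cover at least 67% of the microbial protein and the
#' microbial protein must be at least 80 residues long; a full-length call
#' additionally requires at least 70% coverage of the host protein; alignments
#' whose percent identity exceeds the mean by more than 3 standard deviations
#' are treated as likely human contamination of microbial assemblies; and
#' split-homolog neighbors must be at most 3 feature ranks apart on the same
#' contig and strand.
#'
#' @param microbe_cov_min Minimum fraction of the microbial (query) protein an
#'   alignment must cover. Default 0.67.
#' @param human_cov_min Minimum fraction of the host (subject) protein that an
#'   alignment (full-length) or a neighborhood jointly (split) must cover.
#'   Default 0.70.
#' @param min_microbe_len Minimum microbial protein length in residues.
#'   Default 80.
#' @param contamination_sd_mult Number of standard deviations above the mean
#'   percent identity at which alignments are discarded as contamination.
#'   Default 3.
#' @param max_feature_distance Maximum rank gap (in features) between
#'   neighboring genes of a split homolog. Default 3.
#'
#' @return A list of class `pipeline_params`.
#' @examples
#' pipeline_params(human_cov_min = 0.8)
#' @export
pipeline_params <- function(microbe_cov_min = 0.67,
                            human_cov_min = 0.70,
                            min_microbe_len = 80,
                            contamination_sd_mult = 3,
                            max_feature_distance = 3) {
  p <- list(
    microbe_cov_min = as.numeric(microbe_cov_min),
    human_cov_min = as.numeric(human_cov_min),
    min_microbe_len = as.integer(min_microbe_len),
    contamination_sd_mult = as.numeric(contamination_sd_mult),
    max_feature_distance = as.integer(max_feature_distance)
  )
  validate_params(p)
  structure(p, class = "pipeline_params")
}

validate_params <- function(p) {
  ok_frac <- function(x) is.finite(x) && x > 0 && x <= 1
  if (!ok_frac(p$microbe_cov_min)) {
    abort("`microbe_cov_min` must be in (0, 1]", class = "splithom_validation_error")
  }
  if (!ok_frac(p$human_cov_min)) {
    abort("`human_cov_min` must be in (0, 1]", class = "splithom_validation_error")
  }
  if (is.na(p$min_microbe_len) || p$min_microbe_len < 1) {
    abort("`min_microbe_len` must be >= 1", class = "splithom_validation_error")
  }
  if (!is.finite(p$contamination_sd_mult) || p$contamination_sd_mult <= 0) {
    abort("`contamination_sd_mult` must be > 0", class = "splithom_validation_error")
  }
  if (is.na(p$max_feature_distance) || p$max_feature_distance < 1) {
    abort("`max_feature_distance` must be >= 1", class = "splithom_validation_error")
  }
  invisible(p)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("Homolog pipeline parameters:\n")
  cat(sprintf("  microbe coverage >= %.2f (min length %d aa)\n",
              x$microbe_cov_min, x$min_microbe_len))
  cat(sprintf("  human coverage   >= %.2f\n", x$human_cov_min))
  cat(sprintf("  contamination cutoff: mean + %g SD\n", x$contamination_sd_mult))
  cat(sprintf("  max feature distance: %d\n", x$max_feature_distance))
  invisible(x)
}
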