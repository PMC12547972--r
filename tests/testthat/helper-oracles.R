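# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain loops / enumerations, not via the package's
# own code paths.

# Boolean position-mask union coverage.
oracle_union_cov <- function(start, end, len) {
  mask <- logical(len)
  for (i in seq_along(start)) mask[start[i]:end[i]] <- TRUE
  sum(mask) / len
}

# Two-sided Fisher exact p by full hypergeometric enumeration of tables
# with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n_ <- b + d
  k <- a + b
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written out from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# Faith's PD by walking every selected tip's path to the root and summing
# the union of traversed edges.
oracle_pd <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  stopifnot(!anyNA(idx))
  used <- integer(0)
  for (t in idx) {
    node <- t
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      used <- c(used, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[unique(used)])
}

# Exhaustive split-neighborhood enumeration for one (host, genome) group of
# instances that already satisfy the joint-candidate preconditions: all
# subsets are tested for same contig/strand and chained rank adjacency,
# maximal connected subsets are kept, then the family-count and joint
# coverage predicates are applied. Returns a list of sorted row-index sets.
oracle_neighborhoods <- function(inst, human_cov_min = 0.7, max_gap = 3) {
  n <- nrow(inst)
  subsets <- lapply(seq_len(2^n - 1), function(m) {
    which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
  })
  connected <- Filter(function(idx) {
    s <- inst[idx, , drop = FALSE]
    if (length(unique(s$contig_id)) > 1 || length(unique(s$strand)) > 1) {
      return(FALSE)
    }
    all(diff(sort(s$feature_rank)) <= max_gap)
  }, subsets)
  maximal <- Filter(function(idx) {
    !any(vapply(connected,
                function(j) length(j) > length(idx) && all(idx %in% j),
                logical(1)))
  }, connected)
  keep <- Filter(function(idx) {
    s <- inst[idx, , drop = FALSE]
    length(unique(s$family_id)) >= 2 &&
      oracle_union_cov(s$sstart, s$send, s$slen[1]) >= human_cov_min
  }, maximal)
  lapply(keep, sort)
}

# Minimal HSP tibble builder with sane defaults; any field can be overridden.
make_hsps <- function(...) {
  df <- tibble::tibble(...)
  n <- nrow(df)
  defaults <- list(
    qseqid = sprintf("fam%02d", seq_len(n)), sseqid = "humX",
    pident = 35, qstart = 1L, qend = 100L, qlen = 100L,
    sstart = 1L, send = 100L, slen = 120L,
    evalue = 1e-30, bitscore = 100, gapopen = 0L
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep_len(defaults[[nm]], n)
  }
  df$length <- df$qend - df$qstart + 1L
  df$mismatch <- 0L
  df[, c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
         "qstart", "qend", "sstart", "send", "evalue", "bitscore",
         "qlen", "slen")]
}

# Random joint-candidate-style instance group (all individual coverages
# below the threshold) for the enumeration oracle.
random_instance_group <- function(n, slen = 200L) {
  tibble::tibble(
    human_id = "humX",
    genome_id = "G1",
    contig_id = sample(c("c1", "c2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    feature_rank = sample.int(18L, n),
    gene_id = sprintf("g%02d", seq_len(n)),
    family_id = sample(sprintf("fam%02d", seq_len(max(2, n %/% 1))), n,
                       replace = TRUE),
    sstart = sample.int(slen - 30L, n),
    pident = round(runif(n, 25, 45), 1),
    bitscore = round(runif(n, 50, 200), 1),
    evalue = 1e-30
  ) |>
    dplyr::mutate(
      send = pmin(slen, .data$sstart + sample.int(round(0.65 * slen), n)),
      slen = slen,
      scov = (.data$send - .data$sstart + 1) / slen
    )
}

# Shared default fixture bundle, generated once per test session.
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "splithom-default-fixture")
      if (!dir.exists(dir)) generate_fixture(fixture_config(), dir)
      cache <<- read_bundle(dir)
    }
    cache
  }
})
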