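test_that("coverage is position-count over protein length", {
  hsp <- make_hsps(qseqid = "famA", qstart = 1L, qend = 100L, qlen = 150L,
                   sstart = 10L, send = 39L, slen = 100L)
  expect_equal(coverage_frac(hsp, "query"), 100 / 150)
  expect_equal(coverage_frac(hsp, "subject"), 0.30)
  full <- make_hsps(qseqid = "famB", qstart = 1L, qend = 150L, qlen = 150L)
  expect_equal(coverage_frac(full, "query"), 1.0)
})

test_that("best host hit keeps all HSPs of the top-bitscore pairing with deterministic tie-breaks", {
  hsps <- make_hsps(
    qseqid = c("famA", "famA", "famA", "famB", "famB", "famC", "famC"),
    sseqid = c("humX", "humX", "humY", "humP", "humQ", "humM", "humN"),
    bitscore = c(120, 80, 90, 100, 100, 100, 100),
    evalue = c(1e-30, 1e-10, 1e-25, 1e-30, 1e-20, 1e-30, 1e-30)
  )
  out <- best_human_hit(hsps)
  # famA: humX wins on bitscore; both famA-humX HSPs retained
  expect_equal(sum(out$qseqid == "famA"), 2)
  expect_true(all(out$sseqid[out$qseqid == "famA"] == "humX"))
  # famB: bitscore tie, lower e-value wins
  expect_equal(out$sseqid[out$qseqid == "famB"], "humP")
  # famC: full tie, lexicographically smaller accession wins
  expect_equal(out$sseqid[out$qseqid == "famC"], "humM")
})

test_that("microbe-side filter enforces coverage and minimum length", {
  hsps <- make_hsps(
    qseqid = c("len79", "cov675", "cov66"),
    qstart = c(1L, 1L, 1L), qend = c(79L, 54L, 66L),
    qlen = c(79L, 80L, 100L)
  )
  kept <- filter_microbe_side(hsps, pipeline_params())
  expect_equal(kept$qseqid, "cov675")  # 54/80 = 0.675 >= 0.67
})

test_that("contamination model uses sample SD and mean + 3 SD cutoff", {
  m <- fit_contamination(tibble::tibble(pident = c(20, 30, 40)))
  expect_equal(m$mean_pident, 30)
  expect_equal(m$sd_pident, 10)
  expect_equal(m$cutoff, 60)
  expect_equal(m$n_alignments, 3L)
  expect_equal(tidy(m)$cutoff, 60)

  expect_warning(deg <- fit_contamination(tibble::tibble(pident = c(30, 30))),
                 "degenerate")
  expect_equal(deg$cutoff, 30)

  expect_error(fit_contamination(tibble::tibble(pident = 30)),
               "insufficient", class = "splithom_validation_error")
})

test_that("full-length calls apply host coverage, contamination, and best-per-genome", {
  cm <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       family_id = c("famA", "famA", "famB"))
  feats <- tibble::tibble(
    genome_id = c("G1", "G1", "G2"), contig_id = "c1",
    feature_rank = c(1L, 2L, 1L), strand = "+",
    start = c(100L, 1100L, 100L), end = c(700L, 1700L, 700L),
    gene_id = c("g1", "g2", "g3")
  )
  hsps <- make_hsps(
    qseqid = c("famA", "famB"), sseqid = "humX",
    sstart = c(1L, 1L), send = c(90L, 90L), slen = 120L,  # scov 0.75
    pident = c(40, 56), bitscore = c(100, 110)
  )
  model <- list(cutoff = 55.2)
  calls <- call_full_length(hsps, cm, feats, pipeline_params(), model = model)
  # famB at pident 56 > 55.2 dropped; famA expands to two genes in G1 but
  # only the best per (host, genome) is kept
  expect_equal(nrow(calls), 1)
  expect_equal(calls$genome_id, "G1")
  expect_equal(calls$family_id, "famA")
  expect_equal(calls$human_coverage, 0.75)

  # below-threshold host coverage yields no call
  low <- make_hsps(qseqid = "famA", sseqid = "humX",
                   sstart = 1L, send = 80L, slen = 120L)  # 0.667
  expect_equal(nrow(call_full_length(low, cm, feats, pipeline_params(),
                                     model = model)), 0)
})

test_that("full-length calls match a brute-force row-by-row oracle on random inputs", {
  withr::local_seed(7001)
  params <- pipeline_params()
  for (trial in 1:20) {
    n <- sample(20:60, 1)
    fams <- sprintf("fam%02d", 1:8)
    hsps <- make_hsps(
      qseqid = sample(fams, n, replace = TRUE),
      sseqid = sample(c("humA", "humB", "humC"), n, replace = TRUE),
      pident = round(runif(n, 20, 70), 1),
      bitscore = round(runif(n, 50, 300), 1),
      evalue = signif(10^-runif(n, 5, 60), 3),
      qlen = sample(60:200, n, replace = TRUE),
      slen = 150L
    )
    hsps$qstart <- 1L
    hsps$qend <- vapply(hsps$qlen, function(L) sample.int(L, 1), integer(1))
    hsps$sstart <- sample.int(60, n, replace = TRUE)
    hsps$send <- pmin(150L, hsps$sstart + sample.int(130, n, replace = TRUE))
    cm <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:16),
      family_id = rep(fams, each = 2)
    )
    feats <- tibble::tibble(
      genome_id = rep(c("G1", "G2"), 8), contig_id = "c1",
      feature_rank = rep(1:8, each = 2), strand = "+",
      start = rep(1:8, each = 2) * 1000L, end = rep(1:8, each = 2) * 1000L + 500L,
      gene_id = sprintf("g%02d", 1:16)
    )

    s12 <- filter_microbe_side(best_human_hit(hsps), params)
    model <- tryCatch(
      fit_contamination(s12[coverage_frac(s12, "subject") >= params$human_cov_min, ]),
      error = function(e) NULL)
    if (is.null(model)) next
    calls <- call_full_length(s12, cm, feats, params, model = model)

    # oracle: test every predicate independently per row, then pick the best
    # per (host, genome) by explicit loops
    rows <- list()
    for (i in seq_len(nrow(s12))) {
      r <- s12[i, ]
      scov <- (r$send - r$sstart + 1) / r$slen
      if (scov < params$human_cov_min) next
      if (r$pident > model$cutoff) next
      genes <- cm$gene_id[cm$family_id == r$qseqid]
      for (g in genes) {
        gm <- feats$genome_id[feats$gene_id == g]
        rows[[length(rows) + 1]] <- data.frame(
          human_id = r$sseqid, genome_id = gm, family_id = r$qseqid,
          gene_id = g, bitscore = r$bitscore, evalue = r$evalue)
      }
    }
    if (length(rows) == 0) {
      expect_equal(nrow(calls), 0)
      next
    }
    cand <- do.call(rbind, rows)
    expected <- do.call(rbind, lapply(
      split(cand, paste(cand$human_id, cand$genome_id)),
      function(d) d[order(-d$bitscore, d$evalue, d$gene_id)[1], ]))
    expected <- expected[order(expected$human_id, expected$genome_id), ]
    expect_equal(nrow(calls), nrow(expected))
    expect_equal(calls$gene_id, expected$gene_id)
    expect_equal(calls$human_id, expected$human_id)
    expect_equal(calls$genome_id, expected$genome_id)
  }
})

test_that("raising the host coverage threshold never increases full-length calls", {
  b <- fixture_bundle()
  s12 <- filter_microbe_side(best_human_hit(b$hsps), pipeline_params())
  counts <- vapply(c(0.6, 0.7, 0.8, 0.9), function(hc) {
    p <- pipeline_params(human_cov_min = hc)
    nrow(call_full_length(s12, b$cluster_map, b$features, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
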