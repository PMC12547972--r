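make_instances <- function(rank, family, sstart, send, slen = 150L,
                           contig = "c1", strand = "+", pident = 35,
                           human = "humX", genome = "G1") {
  n <- length(rank)
  tibble::tibble(
    human_id = human, genome_id = genome,
    contig_id = rep_len(contig, n), strand = rep_len(strand, n),
    feature_rank = as.integer(rank), gene_id = sprintf("g%02d", seq_len(n)),
    family_id = family, sstart = as.integer(sstart), send = as.integer(send),
    slen = as.integer(slen), pident = rep_len(pident, n),
    bitscore = 100, evalue = 1e-30,
    scov = (send - sstart + 1) / slen
  )
}

test_that("union coverage matches the position-mask oracle", {
  expect_equal(union_coverage(1, 150, 150), 1.0)
  expect_equal(union_coverage(c(1, 50), c(60, 120), 150), 0.80)
  expect_equal(union_coverage(c(1, 80), c(60, 150), 150), 131 / 150)
  withr::local_seed(7002)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    len <- sample(50:300, 1)
    s <- sample.int(len - 5L, k, replace = TRUE)
    e <- pmin(len, s + sample.int(len %/% 2, k, replace = TRUE))
    expect_equal(union_coverage(s, e, len), oracle_union_cov(s, e, len))
  }
})

test_that("genome expansion keeps only genomes encoding >= 2 distinct aligned families", {
  cm <- tibble::tibble(gene_id = c("a1", "a2", "b1", "c1", "c2", "c3"),
                       family_id = c("famA", "famA", "famB", "famC", "famC", "famC"))
  feats <- tibble::tibble(
    genome_id = c("G1", "G2", "G1", "G3", "G3", "G3"),
    contig_id = "c1", feature_rank = c(1L, 1L, 2L, 1L, 2L, 3L),
    strand = "+", start = c(1L, 1L, 900L, 1L, 900L, 1800L),
    end = c(600L, 600L, 1500L, 600L, 1500L, 2400L),
    gene_id = c("a1", "a2", "b1", "c1", "c2", "c3")
  )
  hsps <- make_hsps(qseqid = c("famA", "famB"), sseqid = "humX",
                    sstart = c(1L, 60L), send = c(70L, 110L), slen = 120L)
  inst <- expand_to_genomes(hsps, cm, feats)
  # famA has genes in G1 and G2 but famB only in G1 -> only G1 retained
  expect_equal(sort(unique(inst$genome_id)), "G1")
  expect_equal(nrow(inst), 2)

  # a single family aligning alone yields nothing
  solo <- make_hsps(qseqid = "famC", sseqid = "humX")
  expect_equal(nrow(expand_to_genomes(solo, cm, feats)), 0)

  # a family with 3 member genes in one genome gives 3 instances
  pair <- make_hsps(qseqid = c("famC", "famA"), sseqid = "humX")
  feats2 <- feats
  feats2$genome_id[feats2$gene_id == "a1"] <- "G3"
  inst3 <- expand_to_genomes(pair, cm, feats2)
  expect_equal(sum(inst3$family_id == "famC" & inst3$genome_id == "G3"), 3)
})

test_that("joint candidates require joint-but-not-individual host coverage", {
  # individuals 0.40 and 0.473, union 131/150 = 0.873: candidate at 70%
  cand <- make_instances(rank = c(1, 2), family = c("famA", "famB"),
                         sstart = c(1, 80), send = c(60, 150))
  expect_equal(nrow(joint_candidates(cand)), 2)

  # one member individually covering 75%: the whole group is excluded
  indiv <- make_instances(rank = c(1, 2), family = c("famA", "famB"),
                          sstart = c(1, 40), send = c(113, 80))
  expect_equal(nrow(joint_candidates(indiv)), 0)

  # union 65% (< 70%): excluded
  low <- make_instances(rank = c(1, 2), family = c("famA", "famB"),
                        sstart = c(1, 53), send = c(52, 97))
  expect_lt(union_coverage(low$sstart, low$send, 150), 0.7)
  expect_equal(nrow(joint_candidates(low)), 0)
})

test_that("neighborhood filter enforces rank gap, strand, contig, and chains components", {
  base <- function(r1, r2, strand = c("+", "+"), contig = c("c1", "c1")) {
    make_instances(rank = c(r1, r2), family = c("famA", "famB"),
                   sstart = c(1, 80), send = c(60, 150),
                   strand = strand, contig = contig)
  }
  expect_equal(nrow(neighborhood_filter(base(5, 8))), 2)   # gap 3 retained
  expect_equal(nrow(neighborhood_filter(base(5, 9))), 0)   # gap 4 rejected
  expect_equal(nrow(neighborhood_filter(base(5, 7, strand = c("+", "-")))), 0)
  expect_equal(nrow(neighborhood_filter(base(5, 7, contig = c("c1", "c2")))), 0)

  # ranks 2,4,6 chain into a single 3-member component
  tri <- make_instances(rank = c(2, 4, 6), family = c("famA", "famB", "famC"),
                        sstart = c(1, 50, 100), send = c(55, 105, 150))
  out <- neighborhood_filter(tri)
  expect_equal(nrow(out), 3)
  expect_equal(dplyr::n_distinct(out$neighborhood_id), 1)
})

test_that("final contamination step removes members and re-tests the neighborhood", {
  model <- list(cutoff = 55.2)
  nb <- make_instances(rank = c(1, 2), family = c("famA", "famB"),
                       sstart = c(1, 80), send = c(60, 150),
                       pident = c(40, 60))
  nb <- neighborhood_filter(nb)
  # the 60%-identity member is removed; the survivor cannot jointly cover
  expect_equal(nrow(finalize_split_calls(nb, model)), 0)

  ok <- make_instances(rank = c(1, 2), family = c("famA", "famB"),
                       sstart = c(1, 80), send = c(60, 150),
                       pident = c(40, 45))
  fin <- finalize_split_calls(neighborhood_filter(ok), model)
  expect_equal(nrow(fin), 2)
  expect_equal(unique(fin$joint_coverage), 131 / 150)

  # removal that drops the union below threshold kills the neighborhood
  tri <- make_instances(rank = c(1, 2, 3), family = c("famA", "famB", "famC"),
                        sstart = c(1, 40, 100), send = c(45, 99, 150),
                        pident = c(40, 60, 45))
  fin3 <- finalize_split_calls(neighborhood_filter(tri), model)
  expect_equal(nrow(fin3), 0)  # remaining union (45+51)/150 = 0.64
})

test_that("split-call invariants hold on the default fixture", {
  b <- fixture_bundle()
  run <- run_pipeline(b)
  sc <- run$split_calls
  grp <- dplyr::group_by(sc, .data$neighborhood_id)
  by_nb <- dplyr::summarise(
    grp,
    n_fam = dplyr::n_distinct(.data$family_id),
    one_gcs = dplyr::n_distinct(paste(.data$genome_id, .data$contig_id,
                                      .data$strand)) == 1,
    max_scov = max(.data$scov),
    joint = .data$joint_coverage[1],
    .groups = "drop")
  expect_true(all(by_nb$n_fam >= 2))
  expect_true(all(by_nb$one_gcs))
  expect_true(all(by_nb$max_scov < run$params$human_cov_min))
  expect_true(all(by_nb$joint >= run$params$human_cov_min))
  expect_true(all(by_nb$joint >= by_nb$max_scov))
  expect_true(all(sc$pident <= run$model$cutoff))
  # filters only shrink
  led <- setNames(run$ledger$n, run$ledger$stage)
  expect_true(led["split_final"] <= led["split_neighborhoods"])
  expect_true(led["split_neighborhoods"] <= led["split_joint_candidates"])
  expect_true(led["split_joint_candidates"] <= led["split_instances"])
})

test_that("neighborhoods equal exhaustive subset enumeration on random groups", {
  withr::local_seed(7003)
  params <- pipeline_params()
  for (trial in 1:60) {
    inst <- random_instance_group(sample(2:9, 1))
    cand <- joint_candidates(inst, params)
    got <- neighborhood_filter(cand, params)
    got_sets <- unname(lapply(
      split(got$gene_id, got$neighborhood_id), function(g) sort(g)))
    exp_sets <- list()
    if (nrow(cand) > 0) {
      exp_idx <- oracle_neighborhoods(cand, params$human_cov_min,
                                      params$max_feature_distance)
      exp_sets <- lapply(exp_idx, function(i) sort(cand$gene_id[i]))
    }
    expect_setequal(got_sets, exp_sets)
  }
})
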