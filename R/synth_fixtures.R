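#' Configuration for the synthetic fixture generator
#'
#' The generator emulates every input the pipeline consumes: a host protein
#' FASTA, per-genome GFF3 feature files, a gene-to-family cluster map,
#' GTDB-style taxonomy, a precomputed 14-column alignment table (synthesized
#' analytically from planted domain correspondences, so coverage fractions
#' are exact by construction), a Newick species tree, a toy ontology with
#' annotations, a reaction table, and a planted-truth table.
#'
#' True homolog identities are drawn uniformly from `pident_range`
#' (25-45%), well below the contamination cutoff; the planted contaminant
#' sits at `contaminant_pident` (90%), far above it. Planted full-length
#' alignments cover 82-95% of the host protein and all of the microbial
#' protein; split members each cover 40-48% of the host with a joint union
#' of at least 83%, so calls are stable across the whole default
#' sensitivity grid.
#'
#' @param seed Integer seed driving the single RNG stream.
#' @param n_planted_full,n_planted_split Numbers of planted full-length and
#'   split cases.
#' @param n_genomes Number of microbial genomes (cases are assigned
#'   round-robin).
#' @param n_background_hosts Host proteins with no alignments (annotation
#'   background).
#' @param pident_range Percent-identity range for true homologs.
#' @param contaminant_pident Percent identity of the planted contaminant.
#' @param host_len_range Host protein length range (residues).
#' @param decoys Include the decoy panel (default `TRUE`).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 42,
                           n_planted_full = 20,
                           n_planted_split = 20,
                           n_genomes = 12,
                           n_background_hosts = 5,
                           pident_range = c(25, 45),
                           contaminant_pident = 90,
                           host_len_range = c(300, 600),
                           decoys = TRUE) {
  cfg <- list(seed = as.integer(seed),
              n_planted_full = as.integer(n_planted_full),
              n_planted_split = as.integer(n_planted_split),
              n_genomes = as.integer(n_genomes),
              n_background_hosts = as.integer(n_background_hosts),
              pident_range = as.numeric(pident_range),
              contaminant_pident = as.numeric(contaminant_pident),
              host_len_range = as.integer(host_len_range),
              decoys = isTRUE(decoys))
  if (any(c(cfg$n_planted_full, cfg$n_planted_split,
            cfg$n_background_hosts) < 0) || cfg$n_genomes < 1) {
    abort("fixture counts must be nonnegative (and n_genomes >= 1)",
          class = "splithom_validation_error")
  }
  if (cfg$contaminant_pident <= max(cfg$pident_range)) {
    abort("contaminant pident must exceed the planted-truth maximum",
          class = "splithom_validation_error")
  }
  structure(cfg, class = "fixture_config")
}

with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# One synthetic HSP row; subject/query coordinates are handed in exactly.
hsp_row <- function(family, host, pident, qstart, qend, qlen,
                    sstart, send, slen, bitscore = NULL) {
  aln <- qend - qstart + 1
  tibble(
    qseqid = family, sseqid = host, pident = pident, length = aln,
    mismatch = as.integer(round(aln * (1 - pident / 100))), gapopen = 1L,
    qstart = as.integer(qstart), qend = as.integer(qend),
    sstart = as.integer(sstart), send = as.integer(send),
    evalue = signif(10^-runif(1, 30, 80), 3),
    bitscore = if (is.null(bitscore)) round(aln * 1.2 + runif(1, 0, 10), 1)
               else bitscore,
    qlen = as.integer(qlen), slen = as.integer(slen)
  )
}

#' Generate the synthetic input bundle with planted truth
#'
#' Writes the complete file bundle under `dir` and returns the planted-truth
#' table. Byte-identical output for identical config and seed. The decoy
#' panel plants one case per rejection mode: a split pair 4 features apart,
#' a pair on opposite strands, a pair on different contigs, a pair with only
#' 65% joint coverage, a single gene covering only 66% of the microbial
#' protein, a 79-residue microbial protein, a 90%-identity contaminant, a
#' pair whose first member individually covers 70% (expected to surface as a
#' full-length call instead), plus a best-host-hit distractor and a split
#' family member stranded in a genome without its partner.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `truth` (tibble `human_id`,
#'   `genome_id`, `expected_call`, `reason`) and the file paths.
#' @export
generate_fixture <- function(config = fixture_config(), dir = tempfile("fixture")) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "gff"), showWarnings = FALSE)
  with_rng_seed(config$seed, build_fixture(config, dir))
}

build_fixture <- function(cfg, dir) {
  genomes <- sprintf("G%03d", seq_len(cfg$n_genomes))
  sp_of_genome <- c(1L, 1L, 2L, 2L, seq(3L, length.out = max(0L, cfg$n_genomes - 4L)))
  sp_of_genome <- sp_of_genome[seq_len(cfg$n_genomes)]
  species <- sprintf("SP%02d", sp_of_genome)
  bact <- c("Lachnospiraceae", "Enterobacteriaceae", "Bacteroidaceae")
  phyl <- c("Firmicutes_A", "Proteobacteria", "Bacteroidota")
  fam_of_sp <- ((seq_len(max(sp_of_genome)) - 1L) %% 3L) + 1L
  taxonomy <- tibble(
    genome_id = genomes, species_id = species,
    lineage = sprintf(
      "d__Bacteria;p__%s;c__ClassA;o__OrderA;f__%s;g__Genus%02d;s__Species %s",
      phyl[fam_of_sp[sp_of_genome]], bact[fam_of_sp[sp_of_genome]],
      sp_of_genome, species)
  )

  # --- case table ------------------------------------------------------
  hosts_full <- sprintf("HFULL%02d", seq_len(cfg$n_planted_full))
  hosts_split <- sprintf("HSPLT%02d", seq_len(cfg$n_planted_split))
  decoy_hosts <- if (cfg$decoys) {
    c("HDGAP4", "HDSTRAND", "HDCONTIG", "HDJOINT65", "HDMCOV66",
      "HDLEN79", "HDCONTAM", "HDINDIV", "HXBEST1", "HXBEST2")
  } else character()
  hosts_bg <- sprintf("HBG%02d", seq_len(cfg$n_background_hosts))
  all_hosts <- c(hosts_full, hosts_split, decoy_hosts, hosts_bg)
  host_len <- setNames(
    as.integer(round(runif(length(all_hosts), cfg$host_len_range[1],
                           cfg$host_len_range[2]))),
    all_hosts)

  cases <- bind_rows(
    tibble(host = hosts_full, type = "full"),
    tibble(host = hosts_split,
           type = c(rep("split", max(0, cfg$n_planted_split - 2)),
                    rep("split3", min(2, cfg$n_planted_split)))),
    if (cfg$decoys) tibble(
      host = c("HDGAP4", "HDSTRAND", "HDCONTIG", "HDJOINT65", "HDMCOV66",
               "HDLEN79", "HDCONTAM", "HDINDIV", "HXBEST1"),
      type = c("gap4", "strand", "contig", "joint65", "mcov66",
               "len79", "contam", "indiv", "besthit"))
  )
  cases$genome <- genomes[((seq_len(nrow(cases)) - 1L) %% cfg$n_genomes) + 1L]

  # genome layouts: ordered gene slots per (genome, contig); fillers pad
  # the gaps so feature ranks are consecutive
  slots <- list()
  add_slot <- function(genome, contig, family, strand = "+") {
    slots[[length(slots) + 1L]] <<-
      list(genome = genome, contig = contig, family = family, strand = strand)
  }
  add_fillers <- function(genome, contig, k) {
    for (i in seq_len(k)) add_slot(genome, contig, NA_character_)
  }

  alignments <- list()
  truth <- list()
  add_truth <- function(host, genome, call, reason) {
    truth[[length(truth) + 1L]] <<-
      tibble(human_id = host, genome_id = genome,
             expected_call = call, reason = reason)
  }

  split_member <- function(family, host, f_lo, f_hi, pid) {
    slen <- host_len[[host]]
    sstart <- max(1L, as.integer(floor(f_lo * slen)))
    send <- min(slen, as.integer(ceiling(f_hi * slen)))
    qlen <- send - sstart + 1L
    hsp_row(family, host, pid, 1L, qlen, qlen, sstart, send, slen)
  }
  draw_pid <- function(n = 1) round(runif(n, cfg$pident_range[1],
                                          cfg$pident_range[2]), 1)

  for (i in seq_len(nrow(cases))) {
    host <- cases$host[i]; type <- cases$type[i]; g <- cases$genome[i]
    slen <- host_len[[host]]
    fam <- function(suffix = "") sprintf("FAM_%s%s", host, suffix)
    add_fillers(g, "CTG1", 3L)
    if (type %in% c("full", "contam", "besthit")) {
      u <- runif(1, 0.82, 0.95)
      aln <- as.integer(ceiling(u * slen))
      sstart <- sample.int(slen - aln + 1L, 1)
      pid <- if (type == "contam") cfg$contaminant_pident else draw_pid()
      bs <- if (type == "besthit") 900 else NULL
      alignments[[length(alignments) + 1L]] <-
        hsp_row(fam(), host, pid, 1L, aln, aln, sstart, sstart + aln - 1L,
                slen, bitscore = bs)
      add_slot(g, "CTG1", fam())
      if (type == "full" && i <= 2) {
        add_fillers(g, "CTG1", 1L)  # second member gene of the same family
        add_slot(g, "CTG1", fam())
      }
      if (type == "besthit") {
        # lower-bitscore alignment to a second host: dropped at best-hit
        slen2 <- host_len[["HXBEST2"]]
        aln2 <- as.integer(ceiling(0.85 * slen2))
        alignments[[length(alignments) + 1L]] <-
          hsp_row(fam(), "HXBEST2", draw_pid(), 1L, aln2, aln2, 1L, aln2,
                  slen2, bitscore = 450)
        add_truth("HXBEST2", g, "none", "decoy:not_best_hit")
        add_truth(host, g, "full", "planted:best_hit")
      } else if (type == "contam") {
        add_truth(host, g, "none", "decoy:contaminant")
      } else {
        add_truth(host, g, "full", "planted:full")
      }
    } else if (type %in% c("split", "split3", "gap4", "strand", "contig",
                           "joint65")) {
      frac <- switch(type,
        joint65 = list(c(0, 0.35), c(0.36, 0.65)),
        split3 = list(c(0, 0.35), c(0.33, 0.62), c(0.60, 0.92)),
        {
          fa <- runif(1, 0.40, 0.48)
          gap <- runif(1, 0.02, 0.05)
          list(c(0, fa), c(fa + gap, runif(1, 0.88, 0.95)))
        })
      pids <- draw_pid(length(frac))
      members <- purrr::imap(frac, function(fr, k) {
        split_member(fam(letters[k]), host, max(fr[1], 1 / slen), fr[2],
                     pids[k])
      })
      alignments <- c(alignments, members)
      gaps <- switch(type,
        gap4 = 4L,
        split3 = sample(1:3, 2, replace = TRUE),
        sample(1:3, length(frac) - 1, replace = TRUE))
      contigs <- rep("CTG1", length(frac))
      strands <- rep("+", length(frac))
      if (type == "strand") strands[2] <- "-"
      if (type == "contig") contigs[2] <- "CTG2"
      for (k in seq_along(frac)) {
        if (k > 1 && contigs[k] == contigs[k - 1]) {
          add_fillers(g, contigs[k], gaps[k - 1] - 1L)
        }
        add_slot(g, contigs[k], fam(letters[k]), strands[k])
      }
      call <- if (type %in% c("split", "split3")) "split" else "none"
      reason <- switch(type,
        split = , split3 = "planted:split",
        gap4 = "decoy:gap4", strand = "decoy:opposite_strand",
        contig = "decoy:different_contig",
        joint65 = "decoy:low_joint_coverage")
      add_truth(host, g, call, reason)
      if (type == "split" && host == hosts_split[1]) {
        # first member's family also has a lone gene elsewhere: no partner,
        # so that genome must yield nothing
        g2 <- genomes[(match(g, genomes) %% cfg$n_genomes) + 1L]
        add_fillers(g2, "CTG1", 2L)
        add_slot(g2, "CTG1", fam("a"))
        add_truth(host, g2, "none", "decoy:lone_partner")
      }
    } else if (type == "mcov66") {
      aln_s <- as.integer(ceiling(0.85 * slen))
      alignments[[length(alignments) + 1L]] <-
        hsp_row(fam(), host, draw_pid(), 1L, 132L, 200L, 1L, aln_s, slen)
      add_slot(g, "CTG1", fam())
      add_truth(host, g, "none", "decoy:low_microbe_coverage")
    } else if (type == "len79") {
      aln_s <- as.integer(ceiling(0.85 * slen))
      alignments[[length(alignments) + 1L]] <-
        hsp_row(fam(), host, draw_pid(), 1L, 79L, 79L, 1L, aln_s, slen)
      add_slot(g, "CTG1", fam())
      add_truth(host, g, "none", "decoy:short_microbe_protein")
    } else if (type == "indiv") {
      a_hi <- 0.75; b_lo <- 0.40; b_hi <- 0.70
      pids <- draw_pid(2)
      alignments <- c(alignments, list(
        split_member(fam("a"), host, 1 / slen, a_hi, pids[1]),
        split_member(fam("b"), host, b_lo, b_hi, pids[2])
      ))
      add_slot(g, "CTG1", fam("a"))
      add_slot(g, "CTG1", fam("b"))
      add_truth(host, g, "full", "decoy:individually_covering")
    }
  }

  hsps <- bind_rows(alignments)
  truth <- bind_rows(truth)

  # --- materialize gene ids, features, cluster map ---------------------
  slot_df <- purrr::map_dfr(slots, as_tibble)
  slot_df <- slot_df %>%
    group_by(.data$genome, .data$contig) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    mutate(gene_id = sprintf("%s_%s_%05d", .data$genome, .data$contig,
                             .data$rank),
           start = 1000L * .data$rank,
           end = 1000L * .data$rank + 600L,
           family = dplyr::coalesce(.data$family,
                                    paste0("FILLFAM_", .data$gene_id)))

  paths <- list(
    alignments = file.path(dir, "alignments.tsv"),
    gff_dir = file.path(dir, "gff"),
    cluster_map = file.path(dir, "cluster_map.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    host_fasta = file.path(dir, "host.faa"),
    tree = file.path(dir, "tree.nwk"),
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    protein_info = file.path(dir, "protein_info.tsv"),
    reactions = file.path(dir, "reactions.tsv"),
    chemicals = file.path(dir, "chemicals.tsv"),
    controller_map = file.path(dir, "controller_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )

  write_alignments(hsps, paths$alignments)
  for (g in unique(slot_df$genome)) {
    rows <- filter(slot_df, .data$genome == g) %>%
      arrange(.data$contig, .data$start)
    writeLines(c(
      "##gff-version 3",
      sprintf("%s\tsplithom\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
              rows$contig, rows$start, rows$end, rows$strand, rows$gene_id)
    ), file.path(paths$gff_dir, paste0(g, ".gff3")))
  }
  readr::write_tsv(slot_df %>% select(gene_id = "gene_id", family_id = "family"),
                   paths$cluster_map, progress = FALSE)
  readr::write_tsv(taxonomy, paths$taxonomy, progress = FALSE)

  seqs <- Biostrings::AAStringSet(vapply(host_len, rand_protein, character(1)))
  names(seqs) <- names(host_len)
  Biostrings::writeXStringSet(seqs, paths$host_fasta)

  n_sp <- max(sp_of_genome)
  tree <- if (n_sp >= 2) {
    ape::rtree(n_sp, tip.label = sprintf("SP%02d", seq_len(n_sp)))
  } else {
    ape::read.tree(text = "(SP01:1,SPOUT:1);")
  }
  ape::write.tree(tree, paths$tree)

  writeLines(fixture_obo(), paths$obo)
  readr::write_tsv(fixture_annotations(hosts_full, hosts_split, hosts_bg),
                   paths$annotations, progress = FALSE)
  readr::write_tsv(
    fixture_protein_info(all_hosts, hosts_full, hosts_split),
    paths$protein_info, progress = FALSE)

  pharm <- fixture_pharm(hosts_split, hosts_full)
  readr::write_tsv(pharm$reactions, paths$reactions, progress = FALSE)
  readr::write_tsv(pharm$chemicals, paths$chemicals, progress = FALSE)
  readr::write_tsv(pharm$controller_map, paths$controller_map, progress = FALSE)

  readr::write_tsv(truth, paths$truth, progress = FALSE)

  invisible(list(dir = dir, truth = truth, paths = paths, config = cfg))
}

# Toy ontology: BP tree with the nucleobase subtree and its excluded
# branches, plus MF oxidoreductase terms; enough structure for propagation,
# the GO-defined gene sets, and enrichment.
fixture_obo <- function() {
  term <- function(id, name, ns, isa = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      paste0("namespace: ", ns),
      if (!is.null(isa)) paste0("is_a: ", isa, " ! parent"), "")
  }
  c("format-version: 1.2", "",
    term("GO:0008150", "biological_process", "biological_process"),
    term("GO:0008152", "metabolic process", "biological_process", "GO:0008150"),
    term("GO:0006805", "xenobiotic metabolic process", "biological_process",
         "GO:0008152"),
    term("GO:0006139", "nucleobase-containing compound metabolic process",
         "biological_process", "GO:0008152"),
    term("GO:0009117", "nucleotide metabolic process", "biological_process",
         "GO:0006139"),
    term("GO:0006637", "acyl-CoA metabolic process", "biological_process",
         "GO:0006139"),
    term("GO:0071616", "acyl-CoA biosynthetic process", "biological_process",
         "GO:0006637"),
    term("GO:0015936", "coenzyme A metabolic process", "biological_process",
         "GO:0006139"),
    term("GO:0046444", "FMN metabolic process", "biological_process",
         "GO:0006139"),
    term("GO:0046443", "FAD metabolic process", "biological_process",
         "GO:0006139"),
    term("GO:0019362", "pyridine nucleotide metabolic process",
         "biological_process", "GO:0006139"),
    term("GO:0003674", "molecular_function", "molecular_function"),
    term("GO:0016491", "oxidoreductase activity", "molecular_function",
         "GO:0003674"),
    term("GO:0016616", "oxidoreductase activity, acting on CH-OH",
         "molecular_function", "GO:0016491"))
}

fixture_annotations <- function(hosts_full, hosts_split, hosts_bg) {
  ev_cycle <- c("IDA", "IEA", "IMP")
  ann <- bind_rows(
    tibble(protein_id = hosts_full, term = "GO:0006805",
           evidence = rep_len(ev_cycle, length(hosts_full))),
    if (length(hosts_full) >= 6) {
      tibble(protein_id = hosts_full[1:6], term = "GO:0016616",
             evidence = "IDA")
    },
    tibble(protein_id = hosts_split, term = "GO:0009117",
           evidence = rep_len(ev_cycle, length(hosts_split))),
    tibble(protein_id = hosts_bg, term = "GO:0008152", evidence = "IEA")
  )
  if (length(hosts_split) >= 4) {
    # one protein in an excluded subtree, one IEA-only protein
    ann <- bind_rows(
      ann,
      tibble(protein_id = hosts_split[3], term = "GO:0071616",
             evidence = "IDA")
    )
    ann$evidence[ann$protein_id == hosts_split[4]] <- "IEA"
  }
  ann$namespace <- ifelse(ann$term %in% c("GO:0016616", "GO:0016491"),
                          "molecular_function", "biological_process")
  ann
}

fixture_protein_info <- function(all_hosts, hosts_full, hosts_split) {
  class_desc <- c(
    "Aldo/keto reductase family",
    "Short-chain dehydrogenases/reductases (SDR) family",
    "Cytochrome P450 family",
    "GST superfamily",
    "UDP-glycosyltransferase family",
    "Arylamine N-acetyltransferase family",
    "'GDXG' lipolytic enzyme family",
    "Type-B carboxylesterase/lipase family",
    "FMO family",
    "Quinone oxidoreductase subfamily")
  desc <- setNames(rep("Uncharacterized protein family", length(all_hosts)),
                   all_hosts)
  desc[hosts_full] <- rep_len(class_desc, length(hosts_full))
  desc[hosts_split] <- "Dihydropyrimidine dehydrogenase family"
  cc <- setNames(rep("Cytoplasm", length(all_hosts)), all_hosts)
  cc[hosts_full] <- rep_len(c("Mitochondrion", "Cytoplasm",
                              "Mitochondrion inner membrane"),
                            length(hosts_full))
  tibble(protein_id = all_hosts, description = unname(desc[all_hosts]),
         cc = unname(cc[all_hosts]))
}

fixture_pharm <- function(hosts_split, hosts_full) {
  reactions <- tibble(
    pathway_id = c("PW1", "PW1", "PW1", "PW1", "PW2", "PW2", "PW2", "PW2"),
    reaction_type = c("Biochemical", "Biochemical", "Transport",
                      "Biochemical", "Biochemical", "Biochemical",
                      "Biochemical", "Biochemical"),
    reactant = c("DrugA", "DrugA", "DrugB", "Homocysteine", "DrugD",
                 "DrugD", "DrugA", "DrugD"),
    product = c("MetabC", "DrugA", "MetabC", "IntermediateZ", "MetabC",
                "MetabE", "MetabC", "MetabC"),
    controller = c("CTRL_A", "CTRL_A", "CTRL_A", "CTRL_B", "unknown",
                   "CTRL_B", "CTRL_FULL", "CTRL_MISS")
  )
  chemicals <- tibble(
    chemical = c("DrugA", "DrugB", "DrugD", "MetabC", "MetabE",
                 "Homocysteine", "IntermediateZ"),
    class = c("Drug", "Prodrug", "Drug", "Metabolite", "Metabolite",
              "Biological Intermediate", "Biological Intermediate")
  )
  pick <- function(v, i, fallback) {
    if (length(v) == 0) fallback else v[min(i, length(v))]
  }
  controller_map <- tibble(
    controller = c("CTRL_A", "CTRL_B", "CTRL_FULL", "CTRL_MISS"),
    human_id = c(pick(hosts_split, 5, "HNONE1"),
                 pick(hosts_split, 6, "HNONE2"),
                 pick(hosts_full, 1, "HNONE3"), "HMISSING")
  )
  list(reactions = reactions, chemicals = chemicals,
       controller_map = controller_map)
}

#' Score recovery of planted homolog calls
#'
#' Exact set comparison of predicted against planted calls at
#' (host protein, genome, call type) granularity.
#'
#' @param full_calls Tibble from [call_full_length()].
#' @param split_calls Tibble from [finalize_split_calls()].
#' @param truth Planted-truth tibble (`human_id`, `genome_id`,
#'   `expected_call`, `reason`).
#' @return Tibble with one row per call type: `type`, `n_truth`, `n_pred`,
#'   `tp`, `precision`, `recall`. Precision is `NA` when nothing was
#'   predicted; recall is 0 then (and `NA` when nothing was planted).
#' @export
score_recovery <- function(full_calls, split_calls, truth) {
  pred <- bind_rows(
    distinct(full_calls, .data$human_id, .data$genome_id) %>%
      mutate(type = "full"),
    distinct(split_calls, .data$human_id, .data$genome_id) %>%
      mutate(type = "split")
  )
  purrr::map_dfr(c("full", "split"), function(ty) {
    tr <- filter(truth, .data$expected_call == ty)
    pr <- filter(pred, .data$type == ty)
    tp <- nrow(semi_join(pr, tr, by = c("human_id", "genome_id")))
    tibble(
      type = ty, n_truth = nrow(tr), n_pred = nrow(pr), tp = tp,
      precision = if (nrow(pr) == 0) NA_real_ else tp / nrow(pr),
      recall = if (nrow(tr) == 0) NA_real_ else tp / nrow(tr)
    )
  })
}
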