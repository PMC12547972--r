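#' Read a protein-protein alignment table
#'
#' Parses the extended 14-column tabular alignment format (the classic
#' 12-column tabular layout plus query and subject lengths, i.e.
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qlen slen`). The query is the microbial protein family and
#' the subject the host protein. Query/subject lengths are required because
#' they are the denominators of every coverage computation downstream.
#'
#' @param path Path to a tab-separated alignment file without header.
#' @return A tibble with one row per HSP and the 14 columns above. Row order
#'   is preserved.
#' @examples
#' f <- tempfile()
#' writeLines("famA\thumX\t33.0\t100\t60\t2\t1\t100\t10\t109\t1e-20\t120\t150\t200", f)
#' read_alignments(f)
#' @export
read_alignments <- function(path) {
  cols <- alignment_columns()
  raw <- readr::read_tsv(
    path,
    col_names = cols,
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", pident = "d", length = "i", mismatch = "i",
      gapopen = "i", qstart = "i", qend = "i", sstart = "i", send = "i",
      evalue = "d", bitscore = "d", qlen = "i", slen = "i"
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) {
    warn(sprintf("alignment file '%s' is empty", path))
    return(raw)
  }
  if (!all(c("qlen", "slen") %in% names(raw)) ||
      any(is.na(raw$qlen)) || any(is.na(raw$slen))) {
    abort("extended tabular required: qlen/slen columns missing or unparsable",
          class = "splithom_io_error")
  }
  validate_alignments(raw)
  raw
}

alignment_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qlen", "slen")
}

#' Validate alignment coordinate invariants
#'
#' Checks `1 <= qstart <= qend <= qlen`, `1 <= sstart <= send <= slen` and
#' `0 <= pident <= 100` for every row, aborting with the offending row number
#' on the first violation.
#'
#' @param hsps Alignment tibble as returned by [read_alignments()].
#' @return The input, invisibly.
#' @export
validate_alignments <- function(hsps) {
  bad <- which(
    !(hsps$qstart >= 1 & hsps$qstart <= hsps$qend & hsps$qend <= hsps$qlen) |
      !(hsps$sstart >= 1 & hsps$sstart <= hsps$send & hsps$send <= hsps$slen) |
      !(hsps$pident >= 0 & hsps$pident <= 100)
  )
  if (length(bad) > 0) {
    abort(sprintf("alignment coordinate invariant violated at row %d", bad[1]),
          class = "splithom_io_error")
  }
  invisible(hsps)
}

#' Write an alignment table
#'
#' Inverse of [read_alignments()]: tab-separated, no header, 14 columns.
#'
#' @param hsps Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(hsps, path) {
  readr::write_tsv(hsps[, alignment_columns()], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read protein-coding features from a GFF3 file
#'
#' Extracts CDS features and assigns each a 1-based rank within its contig by
#' ascending start coordinate, irrespective of strand. Ranks are the
#' "feature distance" coordinate used by split-homolog adjacency filtering.
#'
#' @param gff_path Path to a GFF3 file whose CDS records carry `ID`
#'   attributes.
#' @param genome_id Genome identifier to stamp on every feature.
#' @return A tibble with columns `genome_id`, `contig_id`, `feature_rank`,
#'   `strand`, `start`, `end`, `gene_id`.
#' @export
read_features <- function(gff_path, genome_id) {
  gff <- ape::read.gff(gff_path)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) {
    return(tibble(genome_id = character(), contig_id = character(),
                  feature_rank = integer(), strand = character(),
                  start = integer(), end = integer(), gene_id = character()))
  }
  ids <- stringr::str_match(cds$attributes, "(?:^|;)ID=([^;]+)")[, 2]
  if (any(is.na(ids))) {
    abort("CDS feature without ID attribute", class = "splithom_io_error")
  }
  strand <- as.character(cds$strand)
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    warn(sprintf("skipping %d CDS feature(s) with unknown strand", sum(unknown)))
  }
  tibble(
    genome_id = genome_id,
    contig_id = as.character(cds$seqid),
    strand = strand,
    start = as.integer(cds$start),
    end = as.integer(cds$end),
    gene_id = ids
  )[!unknown, ] %>%
    group_by(.data$contig_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(feature_rank = row_number()) %>%
    ungroup() %>%
    select("genome_id", "contig_id", "feature_rank", "strand",
           "start", "end", "gene_id")
}

#' Read features for a directory of per-genome GFF3 files
#'
#' Expects files named `<genome_id>.gff3` (or `.gff`).
#'
#' @param dir Directory containing the GFF3 files.
#' @return Combined feature tibble across genomes.
#' @export
read_features_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.gff3?$", full.names = TRUE)
  if (length(paths) == 0) {
    abort(sprintf("no GFF3 files found under '%s'", dir),
          class = "splithom_io_error")
  }
  purrr::map_dfr(paths, function(p) {
    read_features(p, sub("\\.gff3?$", "", basename(p)))
  })
}

#' Read a gene-to-family cluster map
#'
#' Two-column TSV (`gene_id`, `family_id`). Every gene must map to exactly one
#' protein family; conflicting duplicates are fatal.
#'
#' @param path Path to the TSV (header optional; detected by column names).
#' @return Tibble with columns `gene_id`, `family_id`.
#' @export
read_cluster_map <- function(path) {
  cm <- read_tsv_flexible(path, c("gene_id", "family_id"))
  cm <- distinct(cm)
  dup <- cm %>% dplyr::count(.data$gene_id) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("gene '%s' maps to multiple families", dup$gene_id[1]),
          class = "splithom_io_error")
  }
  cm
}

#' Read genome taxonomy with GTDB-style lineage strings
#'
#' Parses lineage strings such as
#' `d__Bacteria;p__Firmicutes_A;c__...;o__...;f__Lachnospiraceae;g__...;s__X`
#' into rank columns. If a `species_id` column is absent it is derived from
#' the `s__` field.
#'
#' @param path TSV with columns `genome_id`, `lineage` and optionally
#'   `species_id`.
#' @return Tibble with `genome_id`, `species_id` and rank columns `domain`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `species`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("genome_id", "lineage") %in% names(tax))) {
    abort("taxonomy file must have 'genome_id' and 'lineage' columns",
          class = "splithom_io_error")
  }
  ranks <- parse_gtdb_lineage(tax$lineage)
  out <- dplyr::bind_cols(tax["genome_id"], ranks)
  out$species_id <- if ("species_id" %in% names(tax)) {
    as.character(tax$species_id)
  } else {
    out$species
  }
  if (any(!nzchar(out$phylum) | is.na(out$phylum)) ||
      any(!nzchar(out$family) | is.na(out$family))) {
    abort("taxonomy lineage must provide non-empty phylum and family ranks",
          class = "splithom_io_error")
  }
  select(out, "genome_id", "species_id", "domain", "phylum", "class",
         "order", "family", "genus", "species")
}

#' Parse GTDB lineage strings into rank columns
#'
#' @param lineage Character vector of `d__...;p__...;...;s__...` strings.
#' @return Tibble with columns `domain` through `species` (prefixes removed).
#' @export
parse_gtdb_lineage <- function(lineage) {
  prefixes <- c(domain = "d", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g", species = "s")
  parts <- stringr::str_split(lineage, ";")
  purrr::map_dfr(parts, function(p) {
    p <- stringr::str_trim(p)
    vals <- purrr::imap_chr(prefixes, function(pre, nm) {
      hit <- p[stringr::str_starts(p, paste0(pre, "__"))]
      if (length(hit) == 0) NA_character_ else sub("^.__", "", hit[1])
    })
    as_tibble(as.list(vals))
  })
}

#' Read host protein GO annotations
#'
#' @param path TSV with columns `protein_id`, `term`, `evidence`, `namespace`.
#' @return Tibble with those columns.
#' @export
read_annotations <- function(path) {
  read_tsv_flexible(path, c("protein_id", "term", "evidence", "namespace"))
}

#' Read host protein metadata (family description and cellular component)
#'
#' @param path TSV with columns `protein_id`, `description`, `cc` (free-text
#'   cellular-component annotation, possibly semicolon-separated).
#' @return Tibble with those columns.
#' @export
read_protein_info <- function(path) {
  read_tsv_flexible(path, c("protein_id", "description", "cc"))
}

# Accept either a headered TSV with the expected column names or a headerless
# one with columns in the expected order.
read_tsv_flexible <- function(path, expected) {
  peek <- readr::read_tsv(path, n_max = 1, col_names = FALSE,
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  has_header <- nrow(peek) == 1 && all(expected %in% unlist(peek[1, ]))
  out <- readr::read_tsv(path, col_names = if (has_header) TRUE else expected,
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(expected %in% names(out))) {
    abort(sprintf("'%s' must have columns: %s", path,
                  paste(expected, collapse = ", ")),
          class = "splithom_io_error")
  }
  out[, expected]
}
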