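#' Midpoint-root a species tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path
#' (via `phangorn::midpoint()`). Total branch length is conserved.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "splithom_validation_error")
  }
  if (ape::Ntip(tree) < 2) {
    abort("midpoint rooting needs at least 2 tips",
          class = "splithom_validation_error")
  }
  dm <- ape::cophenetic.phylo(tree)
  if (max(dm) <= 0) {
    abort("longest tip-to-tip path has zero length",
          class = "splithom_validation_error")
  }
  phangorn::midpoint(tree)
}

#' Faith's phylogenetic diversity of a tip subset
#'
#' Sum of branch lengths of the minimal subtree connecting the tips in
#' `tips`, including the path to the root when `include_root = TRUE`
#' (computed with `picante::pd()`).
#'
#' @param tree Rooted `phylo` tree.
#' @param tips Character vector of tip labels (nonempty subset of the tree's
#'   tips).
#' @param include_root Include the path from the subtree to the root
#'   (default `TRUE`).
#' @return Faith's PD as a single number.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "B"))  # 3
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tips <- unique(tips)
  if (length(tips) == 0) {
    abort("tip subset is empty", class = "splithom_validation_error")
  }
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0) {
    abort(sprintf("tips not in tree: %s", paste(unknown, collapse = ", ")),
          class = "splithom_validation_error")
  }
  # picante requires a rooted tree for include.root; resolving a basal
  # multifurcation with zero-length edges leaves PD unchanged
  if (include_root && !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree)
  }
  comm <- matrix(as.integer(tree$tip.label %in% tips), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  picante::pd(comm, tree, include.root = include_root)$PD[1]
}

#' Order xenobiotic classes by Faith's PD, descending
#'
#' @param class_species Named list mapping class key to a character vector of
#'   species (tree tips) where the class was detected.
#' @param tree Rooted `phylo` species tree.
#' @param include_root Passed to [faith_pd()].
#' @return Tibble `class_key`, `n_species`, `pd`, `rank`, sorted by
#'   descending PD with lexicographic tie-break; classes with no species get
#'   PD 0 and rank last.
#' @export
rank_classes_by_pd <- function(class_species, tree, include_root = TRUE) {
  stopifnot(is.list(class_species), !is.null(names(class_species)))
  res <- purrr::imap_dfr(class_species, function(sp, key) {
    sp <- intersect(unique(sp), tree$tip.label)
    tibble(class_key = key, n_species = length(sp),
           pd = if (length(sp) == 0) 0 else faith_pd(tree, sp, include_root))
  })
  res %>%
    arrange(desc(.data$pd), .data$class_key) %>%
    mutate(rank = row_number())
}
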