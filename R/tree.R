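# Sample trees from multiregional presence patterns.
#
# Binary presence characters are used directly: a greedy perfect-phylogeny
# construction accepts presence patterns as clades in order of descending
# sharing count (ties broken lexicographically on the pattern), skipping
# patterns that conflict with the clades accepted so far (their mutations
# are treated as homoplasy and assigned to the smallest accepted clade
# containing them).  On conflict-free (perfect-phylogeny) inputs this
# recovers the unique maximum-parsimony tree; the construction is fully
# deterministic.

#' Build a sample tree from a multiregional mutation profile
#'
#' @param profile an `mr_profile` (see [build_profile()]) or a
#'   logical/numeric presence matrix, variants x samples.
#' @return An object of class `sample_tree`: list with `samples`, `clades`
#'   (each a list with `members` and mutation `count`), `trunk_count`
#'   (founder mutations, carried by the edge between root and the most
#'   recent common ancestor), `leaf_counts` (unique mutations per sample),
#'   `homoplasy` (number of variants whose pattern conflicted), `newick`,
#'   and `phylo` (an [ape::read.tree()] tree whose root-MRCA edge is the
#'   trunk).
#' @export
build_tree <- function(profile) {
  pres <- if (inherits(profile, "mr_profile")) profile$presence else
    profile > 0
  stopifnot(is.matrix(pres))
  ns <- ncol(pres)
  if (ns < 2) stop("at least 2 samples are needed to build a tree",
                   call. = FALSE)
  samples <- colnames(pres)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ns))

  pat <- apply(pres, 1, function(r) paste(as.integer(r), collapse = ""))
  pat <- pat[rowSums(pres) > 0]
  counts <- table(pat)
  full <- paste(rep("1", ns), collapse = "")
  trunk_count <- if (full %in% names(counts)) counts[[full]] else 0L
  counts <- counts[names(counts) != full]

  sizes <- vapply(names(counts), function(p)
    sum(strsplit(p, "")[[1]] == "1"), numeric(1))
  # wider sharing first; among equal-sized conflicting patterns the one
  # backed by more mutations wins (less homoplasy); lexicographic pattern
  # order as the final, deterministic tie-break
  ord <- order(-sizes, -as.numeric(counts), names(counts))

  clades <- list()       # accepted internal clades (size >= 2)
  clade_count <- integer(0)
  leaf_counts <- stats::setNames(integer(ns), samples)
  homoplasy <- 0L

  members_of <- function(p) which(strsplit(p, "")[[1]] == "1")
  laminar <- function(S, C) {
    i <- length(intersect(S, C))
    i == 0 || i == length(S) || i == length(C)
  }

  for (p in names(counts)[ord]) {
    S <- members_of(p)
    w <- counts[[p]]
    if (length(S) == 1L) {
      leaf_counts[S] <- leaf_counts[S] + w
      next
    }
    ok <- all(vapply(clades, function(cl) laminar(S, cl$members),
                     logical(1)))
    if (ok) {
      clades[[length(clades) + 1L]] <- list(members = S, count = w)
    } else {
      # conflicting character: homoplasy; attach its mutations to the
      # smallest accepted clade containing all its samples
      homoplasy <- homoplasy + w
      sup <- Filter(function(cl) all(S %in% cl$members), clades)
      if (length(sup)) {
        sz <- vapply(sup, function(cl) length(cl$members), numeric(1))
        best <- sup[[which.min(sz)]]
        for (i in seq_along(clades)) {
          if (identical(clades[[i]]$members, best$members)) {
            clades[[i]]$count <- clades[[i]]$count + w
            break
          }
        }
      }
      # with no accepted superset the variant hangs off the root clade and
      # contributes to no internal edge
    }
  }

  tree <- structure(list(
    samples = samples,
    clades = clades,
    trunk_count = as.integer(trunk_count),
    leaf_counts = leaf_counts,
    homoplasy = homoplasy
  ), class = "sample_tree")
  tree$newick <- tree_newick(tree)
  tree$phylo <- ape::read.tree(text = tree$newick)
  tree
}

# recursive Newick construction from the laminar clade family
tree_newick <- function(tree) {
  ns <- length(tree$samples)
  clades <- tree$clades
  sets <- lapply(clades, `[[`, "members")
  build <- function(set, budget) {
    # direct children among accepted clades: maximal proper subsets of `set`
    inside <- which(vapply(sets, function(s)
      length(s) < length(set) && all(s %in% set), logical(1)))
    child_sets <- sets[inside]
    maximal <- inside[vapply(seq_along(child_sets), function(i) {
      !any(vapply(seq_along(child_sets), function(j) {
        j != i && length(child_sets[[i]]) < length(child_sets[[j]]) &&
          all(child_sets[[i]] %in% child_sets[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(sets[maximal], use.names = FALSE)
    singles <- setdiff(set, covered)
    parts <- c(
      lapply(maximal, function(i)
        build(sets[[i]], clades[[i]]$count)),
      lapply(singles, function(s)
        sprintf("%s:%d", tree$samples[s], tree$leaf_counts[s]))
    )
    # deterministic child order: by smallest member index
    first <- c(vapply(maximal, function(i) min(sets[[i]]), numeric(1)),
               as.numeric(singles))
    parts <- parts[order(first)]
    sprintf("(%s):%d", paste(unlist(parts), collapse = ","), budget)
  }
  # the outermost group is the most recent common ancestor; the trunk is
  # its root edge
  paste0(build(seq_len(ns), tree$trunk_count), ";")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf(
    "Sample tree over %d samples: trunk %d founder mutations, %d internal clade(s)%s\n",
    length(x$samples), x$trunk_count, length(x$clades),
    if (x$homoplasy > 0) sprintf(", %d homoplasic variant(s)", x$homoplasy)
    else ""))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Sample bipartitions induced by the branches of a sample tree
#'
#' Every edge of the tree below the trunk splits the samples into the
#' leaves descending from it and the rest; the trunk itself (the edge into
#' the most recent common ancestor, i.e. the first branching point) splits
#' off the empty set and is dropped, as are duplicated bipartitions (a
#' clade and its complement induce the same split).
#'
#' @param tree a `sample_tree`.
#' @return List of bipartitions, each a list with `side1`, `side2`
#'   (character vectors of sample ids; together they cover all samples).
#' @export
branch_bipartitions <- function(tree) {
  ns <- length(tree$samples)
  sets <- c(lapply(tree$clades, `[[`, "members"),
            lapply(seq_len(ns), identity))
  out <- list()
  seen <- character(0)
  for (S in sets) {
    if (length(S) == 0 || length(S) == ns) next
    side1 <- sort(S)
    side2 <- sort(setdiff(seq_len(ns), S))
    key <- if (1 %in% side1) paste(side1, collapse = ",") else
      paste(side2, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(side1 = tree$samples[side1],
                                    side2 = tree$samples[side2])
  }
  out
}
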