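#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]) over the defined distances.
#' All pairs must be defined; callers drop records involved in undefined
#' pairs first (see [drop_undefined]). Negative branch-length estimates are
#' clamped to zero. On additive inputs the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param dm a `k2p_dist` object from [distance_matrix], or a plain
#'   symmetric numeric matrix with dimnames.
#' @return An unrooted `phylo` tree with tip labels equal to the matrix
#'   labels.
#' @export
nj_tree <- function(dm) {
  m <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  if (nrow(m) < 3L) stop("neighbor joining needs >= 3 records")
  if (any(!is.finite(m)))
    stop("distance matrix contains undefined pairs; ",
         "drop the records involved first (see drop_undefined)")
  phy <- ape::nj(stats::as.dist(m))
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Drop records involved in undefined distance pairs
#'
#' Greedily removes the record participating in the most undefined pairs
#' until none remain, and subsets the matrix accordingly.
#'
#' @param dm a `k2p_dist` object.
#' @return A list: `dm` (subset `k2p_dist`), `dropped` (accessions removed).
#' @export
drop_undefined <- function(dm) {
  dropped <- character(0)
  while (nrow(dm$undefined_pairs) > 0L) {
    worst <- names(sort(table(c(dm$undefined_pairs)), decreasing = TRUE))[1L]
    keep <- dm$labels != worst
    dm$labels <- dm$labels[keep]
    dm$d <- dm$d[keep, keep, drop = FALSE]
    dm$n_sites <- dm$n_sites[keep, keep, drop = FALSE]
    up <- dm$undefined_pairs
    dm$undefined_pairs <- up[up[, 1] != worst & up[, 2] != worst, ,
                             drop = FALSE]
    dropped <- c(dropped, worst)
  }
  list(dm = dm, dropped = dropped)
}

# Non-trivial bipartitions of an unrooted tree, canonicalised as
# sorted-label strings for the side *not* containing the reference tip
# (first tip label in alphabetical order). Trivial splits (single tip or
# its complement, or all tips) are omitted.
.tree_splits <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  pp <- ape::prop.part(phy)
  out <- character(0)
  for (part in pp) {
    side <- tips[part]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

# As .tree_splits but keyed by internal node number of phy (for mapping
# supports back onto node labels). Returns named character vector
# (names = node ids as character).
.node_splits <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  pp <- ape::prop.part(phy)
  nodes <- n + seq_along(pp)
  out <- rep(NA_character_, length(pp))
  for (i in seq_along(pp)) {
    side <- tips[pp[[i]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    out[i] <- paste(sort(side), collapse = "\r")
  }
  names(out) <- as.character(nodes)
  out
}

#' Column-bootstrap clade supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P distance
#' matrix and NJ tree per replicate, and annotates each internal edge of the
#' tree built from the original alignment with the percentage of successful
#' replicates containing the same leaf bipartition. Replicates in which some
#' pair has no defined K2P distance are dropped and counted; if more than
#' 10% of the requested replicates are dropped the run errors.
#'
#' @param records aligned [barcode_records] (>= 3 rows after QC).
#' @param replicates number of bootstrap replicates (default 1000);
#'   `0` returns the original tree without supports.
#' @param seed optional integer seed for reproducible resampling; `NULL`
#'   continues the current RNG stream.
#' @param deletion passed to [distance_matrix].
#' @return The original-tree `phylo` object with integer `node.label`
#'   supports (empty label on trivial/root nodes) and attributes
#'   `replicates` (successful count) and `dropped`.
#' @export
bootstrap_supports <- function(records, replicates = 1000, seed = NULL,
                               deletion = "pairwise") {
  if (!is.null(seed)) set.seed(seed)
  dm <- distance_matrix(records, deletion = deletion)
  if (nrow(dm$undefined_pairs) > 0L)
    stop("original alignment has undefined pairs; drop those records first")
  phy <- nj_tree(dm)
  if (replicates == 0) return(phy)
  enc <- .encode_alignment(records$sequence)
  node_split <- .node_splits(phy)
  counts <- stats::setNames(rep(0L, length(node_split)), names(node_split))
  L <- ncol(enc)
  dropped <- 0L
  done <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- .k2p_matrices(enc[, cols, drop = FALSE], records$accession)
    if (length(res$undefined) > 0L) {
      dropped <- dropped + 1L
      next
    }
    bt <- ape::nj(stats::as.dist(res$d))
    done <- done + 1L
    splits_b <- .tree_splits(bt)
    hit <- node_split[!is.na(node_split)] %in% splits_b
    counts[!is.na(node_split)][hit] <-
      counts[!is.na(node_split)][hit] + 1L
  }
  if (dropped > 0.1 * replicates)
    stop("more than 10% of bootstrap replicates had undefined distances (",
         dropped, "/", replicates, ")")
  support <- ifelse(is.na(node_split), NA_real_,
                    100 * counts / max(done, 1L))
  phy$node.label <- ifelse(is.na(support), "",
                           as.character(round(support)))
  attr(phy, "replicates") <- done
  attr(phy, "dropped") <- dropped
  phy
}

#' Does a species form an exclusive cluster on the tree?
#'
#' A species is cohesive when its leaves can be separated from all other
#' leaves by removing a single edge (an exclusive clade under some rooting).
#' Singleton species are cohesive by convention. Cohesion here is purely
#' topological; an optional minimum bootstrap support for the separating
#' edge can be required via `min_support` when the tree carries supports.
#'
#' @param tree a `phylo` tree whose tip labels are accessions.
#' @param species species name to test.
#' @param records [barcode_records] mapping accessions to species.
#' @param min_support optional support percentage in (0, 100]; when given,
#'   the separating bipartition must also have at least this support
#'   (requires a tree from [bootstrap_supports]).
#' @return `TRUE` or `FALSE`.
#' @export
is_cohesive <- function(tree, species, records, min_support = NULL) {
  accs <- records$accession[records$species == species]
  accs <- intersect(accs, tree$tip.label)
  if (length(accs) == 0L) stop("species not present in tree: ", species)
  n <- length(tree$tip.label)
  if (length(accs) == 1L || length(accs) >= n - 1L) return(TRUE)
  ref <- sort(tree$tip.label)[1L]
  side <- accs
  if (ref %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "\r")
  node_split <- .node_splits(tree)
  hit <- which(!is.na(node_split) & node_split == key)
  if (length(hit) == 0L) return(FALSE)
  if (!is.null(min_support)) {
    if (is.null(tree$node.label))
      stop("min_support requires a tree with bootstrap supports")
    lab <- tree$node.label[as.integer(names(node_split)[hit]) - n]
    sup <- suppressWarnings(as.numeric(lab))
    return(any(!is.na(sup) & sup >= min_support))
  }
  TRUE
}

#' Write a tree to Newick
#'
#' Branch lengths and integer supports (as internal node labels) are
#' retained; spaces in labels are rendered as underscores.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  tree$tip.label <- gsub(" ", "_", tree$tip.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}
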