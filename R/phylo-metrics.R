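#' Parse a Newick tree string
#'
#' Thin validating wrapper around [ape::read.tree()]: checks bracket
#' balance (reporting the offending character position), requires unique
#' tip labels and branch lengths, and returns a standard `phylo` object.
#'
#' @param text A Newick string (semicolon-terminated) or a length-1 path is
#'   not accepted; use [ape::read.tree()] directly for files.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("malformed Newick: unmatched ')' at position ", i)
  }
  if (depth != 0L) stop("malformed Newick: ", depth, " unclosed '(' at end")
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: missing terminating ';' at position ",
         nchar(text))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: could not parse tree")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  tree
}

#' Cophenetic (patristic) distance matrix
#'
#' Tip-to-tip distances: the sum of branch lengths along the path between
#' each pair of tips. Symmetric with zero diagonal.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A labelled square matrix of distances.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need >= 2 tips")
  ape::cophenetic.phylo(tree)
}

# edge indices on the path from the root down to node (internal or tip)
root_path_edges <- function(tree, node) {
  root <- length(tree$tip.label) + 1L
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  path <- integer(0)
  while (node != root) {
    e <- match(node, child)
    if (is.na(e)) stop("node unreachable from root; tree is not rooted")
    path <- c(path, e)
    node <- parent[e]
  }
  path
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting a set of taxa on
#' a rooted phylogeny. The default (classic rooted convention) includes the
#' path down to the root; `rooted = FALSE` instead spans only the taxa
#' themselves (dropping the stem above their most recent common ancestor),
#' which gives 0 for a single taxon.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param taxa Character vector of tip labels (subset of `tree$tip.label`).
#' @param rooted Include the root connection (default `TRUE`).
#' @return PD in branch-length units.
#' @examples
#' toy <- parse_newick("((A:1,B:1):1,(C:2,D:2):1);")
#' faith_pd(toy, c("A", "B"))  # 3
#' faith_pd(toy, toy$tip.label)  # 8, the total branch length
#' @export
faith_pd <- function(tree, taxa, rooted = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) < 1L) stop("'taxa' must contain at least one tip")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  tips <- match(taxa, tree$tip.label)
  edges <- unique(unlist(lapply(tips, root_path_edges, tree = tree)))
  if (!rooted) {
    # drop the shared stem: edges present on every tip's root path
    shared <- Reduce(intersect, lapply(tips, root_path_edges, tree = tree))
    edges <- setdiff(edges, shared)
  }
  sum(tree$edge.length[edges])
}

check_taxa_in_matrix <- function(D, taxa) {
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, rownames(D))
  if (length(unknown)) {
    stop("taxa not in distance matrix: ", paste(unknown, collapse = ", "))
  }
  taxa
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Mean cophenetic distance over all unordered pairs of a community's
#' species (presence-based, unweighted by abundance).
#'
#' @param D Cophenetic distance matrix (labelled, symmetric).
#' @param taxa Tip labels of the community's species; at least 2 for a
#'   defined value.
#' @return MPD in branch-length units; `NaN` with a warning if fewer than 2
#'   taxa.
#' @export
mpd <- function(D, taxa) {
  taxa <- check_taxa_in_matrix(D, taxa)
  if (length(taxa) < 2L) {
    warning("MPD undefined for fewer than 2 taxa")
    return(NaN)
  }
  sub <- D[taxa, taxa]
  mean(sub[upper.tri(sub)])
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean, over the community's species, of each species' cophenetic distance
#' to its nearest co-occurring relative.
#'
#' @inheritParams mpd
#' @return MNTD; `NaN` with a warning if fewer than 2 taxa.
#' @export
mntd <- function(D, taxa) {
  taxa <- check_taxa_in_matrix(D, taxa)
  if (length(taxa) < 2L) {
    warning("MNTD undefined for fewer than 2 taxa")
    return(NaN)
  }
  sub <- D[taxa, taxa]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' Faith's PD for every row of a community matrix
#'
#' @param comm Community matrix (patches x species, abundances).
#' @param tree Rooted `phylo` whose tips cover the matrix's species.
#' @param rooted Passed to [faith_pd()].
#' @return data.frame with `patch_id` and `PD`.
#' @export
community_pd <- function(comm, tree, rooted = TRUE) {
  comm <- as.matrix(comm)
  sp <- colnames(comm)
  if (is.null(sp)) stop("community matrix must have species column names")
  ids <- rownames(comm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(comm)))
  pd <- vapply(seq_len(nrow(comm)), function(i) {
    present <- sp[comm[i, ] > 0]
    if (length(present) == 0L) return(NaN)
    faith_pd(tree, present, rooted = rooted)
  }, numeric(1))
  data.frame(patch_id = ids, PD = pd)
}
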