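# shared fixtures and independent oracles

# 4-taxon toy tree: d(A,B)=2, d(C,D)=4, cross-clade distances 5
toy_tree <- function() parse_newick("((A:1,B:1):1,(C:2,D:2):1);")

# brute-force MPD: explicit double loop over ordered pairs
oracle_mpd <- function(D, taxa) {
  s <- 0; np <- 0
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (i < j) {
        s <- s + D[taxa[i], taxa[j]]
        np <- np + 1
      }
    }
  }
  s / np
}

# brute-force MNTD: per-taxon scan for the nearest other member
oracle_mntd <- function(D, taxa) {
  nn <- vapply(taxa, function(a) {
    min(vapply(setdiff(taxa, a), function(b) D[a, b], numeric(1)))
  }, numeric(1))
  mean(nn)
}

# independent Faith's PD: sum, over edges, of the edge length whenever the
# edge subtends at least one focal tip (rooted convention)
oracle_pd_rooted <- function(tree, taxa) {
  tips_below <- function(node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  keep <- vapply(seq_len(nrow(tree$edge)), function(e) {
    any(tips_below(tree$edge[e, 2]) %in% taxa)
  }, logical(1))
  sum(tree$edge.length[keep])
}

# flood-fill connectivity oracle: repeated neighborhood dilation inside one
# labelled component, checking it is reached from its first cell
oracle_component_connected <- function(labels, id, connectivity) {
  mask <- labels == id
  seed <- which(mask, arr.ind = TRUE)[1, , drop = FALSE]
  reach <- matrix(FALSE, nrow(labels), ncol(labels))
  reach[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- reach
    idx <- which(reach, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      nb <- if (connectivity == 4) {
        rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      } else {
        expand.grid(i + (-1:1), j + (-1:1))
      }
      for (r2 in seq_len(nrow(nb))) {
        a <- nb[r2, 1]; b <- nb[r2, 2]
        if (a >= 1 && a <= nrow(labels) && b >= 1 && b <= ncol(labels) &&
            mask[a, b]) grown[a, b] <- TRUE
      }
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[mask])
}

# small deterministic random tree for parameterised cases
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n, tip.label = sprintf("t%02d", seq_len(n)))
}
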