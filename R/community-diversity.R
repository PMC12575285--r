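as_abundance <- function(community) {
  if (!is.numeric(community)) stop("'community' must be numeric abundances")
  if (any(community < 0)) stop("abundances must be >= 0")
  community
}

#' Species richness
#'
#' Number of species with abundance > 0.
#'
#' @param community Numeric vector of abundances (optionally named by
#'   species).
#' @return Integer richness; 0 for an empty community.
#' @export
richness <- function(community) {
  sum(as_abundance(community) > 0)
}

#' Shannon-Wiener diversity
#'
#' `H' = -sum p_i log2(p_i)` over species with positive abundance, where
#' `p_i = N_i / N`. The default base-2 logarithm returns bits; `base` can
#' switch to natural log (nats).
#'
#' @inheritParams richness
#' @param base Logarithm base, default 2.
#' @return H' in units of `log base`; `NaN` for an empty community.
#' @examples
#' shannon(c(1, 1, 2))  # 1.5 bits
#' @export
shannon <- function(community, base = 2) {
  x <- as_abundance(community)
  x <- x[x > 0]
  if (length(x) == 0L) {
    warning("empty community: Shannon index undefined")
    return(NaN)
  }
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' Pielou evenness
#'
#' `E = H' / ln(S)` with H' in bits (base 2) — the mixed-base form as used
#' in field tables, which can exceed 1 (uniform communities give
#' `log2(S)/ln(S) = 1/ln 2 = 1.4427`). Set `consistent_base = TRUE` to
#' divide by `log2(S)` instead, bounding E by 1.
#'
#' @inheritParams richness
#' @param consistent_base If `TRUE`, use log2 in the denominator so that a
#'   perfectly even community scores exactly 1.
#' @return Evenness; `NaN` when S < 2 (ln 1 = 0).
#' @export
pielou <- function(community, consistent_base = FALSE) {
  s <- richness(community)
  if (s < 2) {
    warning("Pielou evenness undefined for fewer than 2 species")
    return(NaN)
  }
  h <- shannon(community, base = 2)
  h / if (consistent_base) log2(s) else log(s)
}

#' Per-patch taxonomic diversity table
#'
#' Richness, Shannon-Wiener (bits) and Pielou evenness for every row of a
#' community matrix.
#'
#' @param comm Community matrix: rows = patches, columns = species,
#'   non-negative integer abundances; rownames are patch ids.
#' @param consistent_base Passed to [pielou()].
#' @return data.frame with columns `patch_id`, `R`, `H`, `E`.
#' @export
taxonomic_diversity <- function(comm, consistent_base = FALSE) {
  comm <- as.matrix(comm)
  ids <- rownames(comm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(comm)))
  rows <- lapply(seq_len(nrow(comm)), function(i) {
    x <- comm[i, ]
    data.frame(patch_id = ids[i], R = richness(x),
               H = suppressWarnings(shannon(x)),
               E = suppressWarnings(pielou(x, consistent_base)))
  })
  do.call(rbind, rows)
}
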