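metric_fun <- function(metric) {
  metric <- match.arg(metric, c("MPD", "MNTD"))
  if (metric == "MPD") mpd else mntd
}

#' Tip-shuffle null distribution for MPD or MNTD
#'
#' Builds the random-assembly null for a community of size `k` by uniformly
#' permuting the tip labels of the phylogeny and recomputing the metric for
#' the focal community each time. Because the community identity is
#' arbitrary under a full shuffle, each replicate is equivalent to
#' evaluating the metric on a uniform random k-subset of tips, which is how
#' it is drawn here.
#'
#' @param D Cophenetic distance matrix (labelled).
#' @param k Community size, `2 <= k <= n_tips`.
#' @param n_perm Number of permutation replicates (default 999).
#' @param seed Integer seed; required for reproducibility.
#' @param metric `"MPD"` or `"MNTD"`.
#' @param population_sd Use the n-denominator SD for `null_sd`.
#' @return List of class `null_distribution`: `metric`, `replicates`
#'   (length `n_perm`), `null_mean`, `null_sd` (sample SD by default).
#' @export
tip_shuffle_null <- function(D, k, n_perm = 999, seed, metric = "MPD",
                             population_sd = FALSE) {
  n <- nrow(D)
  if (k < 2 || k > n) stop("'k' must be in [2, n_tips = ", n, "]")
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (missing(seed)) stop("'seed' is required")
  fn <- metric_fun(metric)
  tips <- rownames(D)
  set.seed(seed)
  reps <- vapply(seq_len(n_perm), function(i) fn(D, sample(tips, k)),
                 numeric(1))
  s <- stats::sd(reps)
  if (population_sd) s <- s * sqrt((n_perm - 1) / n_perm)
  if (n_perm == 1L) s <- 0
  structure(list(metric = metric, replicates = reps, null_mean = mean(reps),
                 null_sd = s),
            class = "null_distribution")
}

#' Exact null moments by exhaustive subset enumeration
#'
#' Evaluates MPD or MNTD on every k-subset of tips and returns the exact
#' mean and sample SD — the test oracle for [tip_shuffle_null()]. Refuses
#' when `choose(n, k)` exceeds `max_subsets`.
#'
#' @inheritParams tip_shuffle_null
#' @param max_subsets Enumeration budget (default 1e6).
#' @return List: `mean`, `sd` (sample SD over the enumerated subsets),
#'   `pop_sd` (the exact SD of the null distribution itself, i.e. the
#'   n-denominator SD — what a permutation estimate converges to),
#'   `values`, `n_subsets`.
#' @export
exhaustive_null <- function(D, k, metric = "MPD", max_subsets = 1e6) {
  n <- nrow(D)
  if (k < 2 || k > n) stop("'k' must be in [2, n_tips = ", n, "]")
  n_sub <- choose(n, k)
  if (n_sub > max_subsets) {
    stop("choose(", n, ", ", k, ") = ", n_sub, " exceeds the enumeration ",
         "bound of ", max_subsets)
  }
  fn <- metric_fun(metric)
  tips <- rownames(D)
  subsets <- utils::combn(tips, k, simplify = FALSE)
  vals <- vapply(subsets, function(s) fn(D, s), numeric(1))
  m <- length(vals)
  s <- if (m > 1L) stats::sd(vals) else 0
  list(mean = mean(vals), sd = s, pop_sd = s * sqrt((m - 1) / m),
       values = vals, n_subsets = m)
}

ses_z <- function(obs, null_mean, null_sd, sd_tol = 1e-12) {
  if (!is.finite(obs)) return(NaN)
  if (null_sd < sd_tol) {
    warning("null SD below tolerance (", sd_tol, "); SES undefined")
    return(NaN)
  }
  -1 * (obs - null_mean) / null_sd
}

#' Net relatedness index (NRI)
#'
#' `NRI = -1 * (MPD_obs - mean(MPD_null)) / SD(MPD_null)` under the
#' tip-shuffle null. Positive values indicate phylogenetic clustering
#' (co-occurring species more related than random), negative values
#' overdispersion.
#'
#' @inheritParams tip_shuffle_null
#' @param taxa Community tip labels (>= 2).
#' @return z-score; `NaN` when the null SD is degenerate (< 1e-12).
#' @export
nri <- function(D, taxa, n_perm = 999, seed, population_sd = FALSE) {
  taxa <- check_taxa_in_matrix(D, taxa)
  obs <- mpd(D, taxa)
  null <- tip_shuffle_null(D, length(taxa), n_perm, seed, "MPD",
                           population_sd)
  ses_z(obs, null$null_mean, null$null_sd)
}

#' Nearest taxon index (NTI)
#'
#' `NTI = -1 * (MNTD_obs - mean(MNTD_null)) / SD(MNTD_null)` under the
#' tip-shuffle null; the nearest-neighbor analogue of [nri()].
#'
#' @inheritParams nri
#' @return z-score; `NaN` when the null SD is degenerate.
#' @export
nti <- function(D, taxa, n_perm = 999, seed, population_sd = FALSE) {
  taxa <- check_taxa_in_matrix(D, taxa)
  obs <- mntd(D, taxa)
  null <- tip_shuffle_null(D, length(taxa), n_perm, seed, "MNTD",
                           population_sd)
  ses_z(obs, null$null_mean, null$null_sd)
}

#' Interpret phylogenetic structure from NRI and NTI
#'
#' Sign rule: both positive -> clustered (consistent with environmental
#' filtering); both negative -> dispersed (competitive exclusion / niche
#' differentiation); mixed signs -> random. A companion flag marks results
#' whose |z| stays below 1.96 as not individually significant.
#'
#' @param nri,nti z-scores (vectorised).
#' @return data.frame with `label` in
#'   `{"clustered", "dispersed", "random", "undefined"}` and `significant`
#'   (both |z| >= 1.96).
#' @export
interpret_structure <- function(nri, nti) {
  lab <- ifelse(!is.finite(nri) | !is.finite(nti), "undefined",
                ifelse(nri > 0 & nti > 0, "clustered",
                       ifelse(nri < 0 & nti < 0, "dispersed", "random")))
  sig <- is.finite(nri) & is.finite(nti) & abs(nri) >= 1.96 & abs(nti) >= 1.96
  data.frame(label = lab, significant = sig)
}

#' Phylogenetic structure table for a community matrix
#'
#' Observed MPD/MNTD, NRI, NTI and the structure label for every patch.
#' Null distributions depend only on community richness, so one null per
#' distinct richness value is computed and shared across patches — identical
#' results to per-patch nulls at a fraction of the cost.
#'
#' @param comm Community matrix (patches x species).
#' @param tree Rooted `phylo` covering the matrix's species, or a
#'   precomputed cophenetic matrix.
#' @param n_perm Permutations per null (default 999).
#' @param seed Integer seed.
#' @param population_sd Use population SD in the null denominators.
#' @return data.frame: `patch_id`, `R`, `MPD_obs`, `MNTD_obs`, `NRI`,
#'   `NTI`, `label`, `significant`. Patches with R < 2 carry `NaN` scores
#'   and label `"undefined"`.
#' @export
phylo_structure <- function(comm, tree, n_perm = 999, seed,
                            population_sd = FALSE) {
  if (missing(seed)) stop("'seed' is required")
  comm <- as.matrix(comm)
  sp <- colnames(comm)
  if (is.null(sp)) stop("community matrix must have species column names")
  D <- if (inherits(tree, "phylo")) cophenetic_matrix(tree) else as.matrix(tree)
  check_taxa_in_matrix(D, sp)
  ids <- rownames(comm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(comm)))
  rich <- rowSums(comm > 0)
  ks <- sort(unique(rich[rich >= 2]))
  nulls <- list()
  for (i in seq_along(ks)) {
    # distinct sub-seed per richness class, kept within 32-bit range
    nulls[[as.character(ks[i])]] <- list(
      MPD = tip_shuffle_null(D, ks[i], n_perm, (seed + 7L * i) %% 2147483647L,
                             "MPD", population_sd),
      MNTD = tip_shuffle_null(D, ks[i], n_perm, (seed + 11L * i) %% 2147483647L,
                              "MNTD", population_sd))
  }
  res <- lapply(seq_len(nrow(comm)), function(i) {
    present <- sp[comm[i, ] > 0]
    if (length(present) < 2L) {
      return(data.frame(patch_id = ids[i], R = length(present),
                        MPD_obs = NaN, MNTD_obs = NaN, NRI = NaN, NTI = NaN))
    }
    nk <- nulls[[as.character(length(present))]]
    obs_mpd <- mpd(D, present)
    obs_mntd <- mntd(D, present)
    data.frame(patch_id = ids[i], R = length(present),
               MPD_obs = obs_mpd, MNTD_obs = obs_mntd,
               NRI = ses_z(obs_mpd, nk$MPD$null_mean, nk$MPD$null_sd),
               NTI = ses_z(obs_mntd, nk$MNTD$null_mean, nk$MNTD$null_sd))
  })
  out <- do.call(rbind, res)
  cbind(out, interpret_structure(out$NRI, out$NTI))
}
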