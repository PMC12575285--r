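#' Synthetic-data configuration
#'
#' Bundles every knob of the synthetic generators, with defaults matching
#' the field protocol the package emulates: a 10 m x 10 m plot sampled on a
#' 26 x 26 grid of 0.39 m cells, fragmented soil cover, right-skewed soil
#' depths with strong variability, and communities whose richness rises
#' with log10 patch area.
#'
#' @param n_rows,n_cols Grid dimensions (default 26 x 26 = 676 points).
#' @param cell_side Cell side in metres (default 0.39).
#' @param rock_fraction Fraction of cells that are exposed rock, in
#'   \[0, 1\] (default 0.4, giving fragmented soil cover).
#' @param clumping Non-negative box-smoothing radius in cells applied to
#'   the rock noise field; larger values aggregate rock into fewer, larger
#'   outcrops (default 2).
#' @param depth_mean Mean soil depth in cm (default 24.27).
#' @param depth_cv CV of soil depth (default 0.53, strong variability).
#' @param swc_mean,swc_cv Soil water content mean (%) and CV
#'   (defaults 17.17, 0.37).
#' @param tc_mean,tc_cv Total carbon mean (g/kg) and CV (defaults 1.82,
#'   0.18).
#' @param tn_mean,tn_cv Total nitrogen mean (g/kg) and CV (defaults 0.23,
#'   0.14).
#' @param quadrats_per_patch Soil-sampling quadrats simulated per patch
#'   (default 4; the field intensity per patch area is not standardized, so
#'   it is a free parameter).
#' @param n_taxa Species-pool size (default 98).
#' @param richness_intercept,richness_slope Expected richness model
#'   `E[R] = intercept + slope * log10(PA m2)` (defaults 10 and 8).
#' @param assembly_mode `"random"`, `"filtered"` (clade filter ->
#'   clustering) or `"overdispersed"` (maximin spacing -> dispersion).
#' @param filter_strength Non-negative decay rate of the clade filter
#'   (default 1).
#' @param seed Integer seed; the generators are pure functions of
#'   (config, seed).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_rows = 26L, n_cols = 26L, cell_side = 0.39,
                         rock_fraction = 0.4, clumping = 2L,
                         depth_mean = 24.27, depth_cv = 0.53,
                         swc_mean = 17.17, swc_cv = 0.37,
                         tc_mean = 1.82, tc_cv = 0.18,
                         tn_mean = 0.23, tn_cv = 0.14,
                         quadrats_per_patch = 4L,
                         n_taxa = 98L, richness_intercept = 10,
                         richness_slope = 8,
                         assembly_mode = c("random", "filtered",
                                           "overdispersed"),
                         filter_strength = 1, seed = 1L) {
  assembly_mode <- match.arg(assembly_mode)
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_side = cell_side, rock_fraction = rock_fraction,
              clumping = as.integer(clumping), depth_mean = depth_mean,
              depth_cv = depth_cv, swc_mean = swc_mean, swc_cv = swc_cv,
              tc_mean = tc_mean, tc_cv = tc_cv, tn_mean = tn_mean,
              tn_cv = tn_cv,
              quadrats_per_patch = as.integer(quadrats_per_patch),
              n_taxa = as.integer(n_taxa),
              richness_intercept = richness_intercept,
              richness_slope = richness_slope,
              assembly_mode = assembly_mode,
              filter_strength = filter_strength, seed = as.integer(seed))
  if (cfg$n_rows < 1L || cfg$n_cols < 1L) stop("grid dimensions must be >= 1")
  if (cfg$rock_fraction < 0 || cfg$rock_fraction > 1) {
    stop("'rock_fraction' must be in [0, 1]")
  }
  if (cfg$clumping < 0L) stop("'clumping' must be >= 0")
  if (cfg$depth_mean <= 0) stop("'depth_mean' must be positive")
  if (cfg$depth_cv < 0) stop("'depth_cv' must be >= 0")
  if (cfg$n_taxa < 2L) stop("'n_taxa' must be >= 2")
  if (cfg$filter_strength < 0) stop("'filter_strength' must be >= 0")
  if (cfg$quadrats_per_patch < 1L) stop("'quadrats_per_patch' must be >= 1")
  structure(cfg, class = "synth_config")
}

# lognormal draws with prescribed arithmetic mean and CV; cv = 0 degenerates
# to the constant mean
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a random ultrametric phylogeny
#'
#' A seeded coalescent tree ([ape::rcoal()]) rescaled to a root depth of
#' 100 branch-length units, standing in for a dated species-level
#' phylogeny. Tips are labelled `sp001`, `sp002`, ...
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; the same seed yields a byte-identical Newick
#'   serialization.
#' @return A rooted bifurcating `phylo` with strictly positive branch
#'   lengths.
#' @export
gen_tree <- function(n_taxa, seed) {
  if (n_taxa < 2) stop("'n_taxa' must be >= 2")
  set.seed(seed)
  tree <- ape::rcoal(n_taxa,
                     tip.label = sprintf("sp%03d", seq_len(n_taxa)))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (100 / depth)
  tree
}

#' Generate a synthetic soil-depth grid
#'
#' Rock placement: uniform noise box-smoothed with radius `clumping`, then
#' the lowest `rock_fraction` quantile of the smoothed field becomes rock,
#' so the realized rock fraction is exact up to cell discretization.
#' Smoothing spatially aggregates rock, producing fewer and larger soil
#' patches at equal rock fraction. Soil depths are lognormal with the
#' configured mean and CV.
#'
#' @param config A [synth_config()].
#' @return A [soil_grid()].
#' @export
gen_soil_grid <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  noise <- matrix(stats::runif(nr * nc), nr, nc)
  field <- box_smooth(noise, config$clumping)
  n_rock <- round(config$rock_fraction * nr * nc)
  rock <- matrix(FALSE, nr, nc)
  if (n_rock > 0L) rock[order(field)[seq_len(n_rock)]] <- TRUE
  depths <- matrix(0, nr, nc)
  n_soil <- sum(!rock)
  if (n_soil > 0L) {
    depths[!rock] <- rlnorm_mean_cv(n_soil, config$depth_mean,
                                    config$depth_cv)
  }
  soil_grid(depths, config$cell_side)
}

# box (moving-average) smoothing with truncated windows at the borders
box_smooth <- function(mat, radius) {
  if (radius == 0L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - radius):min(nr, i + radius)
    for (j in seq_len(nc)) {
      rj <- max(1L, j - radius):min(nc, j + radius)
      out[i, j] <- mean(mat[ri, rj])
    }
  }
  out
}

#' Generate per-patch soil quadrat samples
#'
#' Simulates `quadrats_per_patch` soil-sampling quadrats in every patch of
#' a patch map. Depth, water content, carbon and nitrogen are independent
#' lognormal draws with the configured means and CVs, so realized per-patch
#' means and CVs fluctuate around the targets with quadrat-sampling noise.
#'
#' @param patch_map A `patch_map` with at least one patch.
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return data.frame with columns `patch_id`, `quadrat`, `Sd_cm`,
#'   `SWC_pct`, `TC_gkg`, `TN_gkg`.
#' @export
gen_resource_samples <- function(patch_map, config, seed = config$seed) {
  stopifnot(inherits(patch_map, "patch_map"), inherits(config, "synth_config"))
  if (patch_map$n_patches < 1L) stop("patch map has no patches")
  set.seed(seed)
  q <- config$quadrats_per_patch
  ids <- rep(seq_len(patch_map$n_patches), each = q)
  n <- length(ids)
  data.frame(patch_id = ids,
             quadrat = rep(seq_len(q), times = patch_map$n_patches),
             Sd_cm = rlnorm_mean_cv(n, config$depth_mean, config$depth_cv),
             SWC_pct = rlnorm_mean_cv(n, config$swc_mean, config$swc_cv),
             TC_gkg = rlnorm_mean_cv(n, config$tc_mean, config$tc_cv),
             TN_gkg = rlnorm_mean_cv(n, config$tn_mean, config$tn_cv))
}

#' Generate patch communities on a phylogeny
#'
#' Richness per patch is drawn Poisson with expectation
#' `richness_intercept + richness_slope * log10(PA)`, clipped to
#' `[1, n_taxa]` (out-of-range targets are clipped with a warning).
#' Species are then selected according to `assembly_mode`:
#' \describe{
#'   \item{random}{uniform draws from the pool — stochastic assembly.}
#'   \item{filtered}{draws weighted by `exp(-filter_strength * d / mean(d))`
#'     where `d` is cophenetic distance to a randomly chosen focal tip —
#'     a minimal clade-filter (environmental filtering) model producing
#'     phylogenetic clustering.}
#'   \item{overdispersed}{greedy maximin spacing: starting from a random
#'     tip, each added species maximizes its nearest-neighbor distance to
#'     the species already chosen — producing phylogenetic dispersion.}
#' }
#' Abundances are skewed positive integers (1 + negative binomial).
#'
#' @param patches data.frame with columns `patch_id` and `PA_m2`, e.g. from
#'   [patch_metrics()].
#' @param tree Phylogeny whose tips form the species pool.
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Integer community matrix, patches x species, with dimnames.
#' @export
gen_communities <- function(patches, tree, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(patches) == 0L) stop("'patches' is empty")
  if (!all(c("patch_id", "PA_m2") %in% names(patches))) {
    stop("'patches' needs columns patch_id and PA_m2")
  }
  tips <- tree$tip.label
  n_pool <- length(tips)
  D <- cophenetic_matrix(tree)
  d_scale <- mean(D[upper.tri(D)])
  set.seed(seed)
  target <- config$richness_intercept +
    config$richness_slope * log10(patches$PA_m2)
  if (any(target < 1)) {
    warning(sum(target < 1), " patch(es) had expected richness < 1; ",
            "clipped to 1")
    target <- pmax(target, 1)
  }
  comm <- matrix(0L, nrow(patches), n_pool,
                 dimnames = list(as.character(patches$patch_id), tips))
  for (i in seq_len(nrow(patches))) {
    s <- stats::rpois(1L, target[i])
    s <- min(max(s, 1L), n_pool)
    chosen <- switch(config$assembly_mode,
      random = sample(tips, s),
      filtered = {
        focal <- sample(tips, 1L)
        w <- exp(-config$filter_strength * D[, focal] / d_scale)
        sample(tips, s, prob = w)
      },
      overdispersed = {
        sel <- sample(tips, 1L)
        while (length(sel) < s) {
          cand <- setdiff(tips, sel)
          nn <- apply(D[cand, sel, drop = FALSE], 1L, min)
          sel <- c(sel, cand[which.max(nn)])
        }
        sel
      })
    comm[i, chosen] <- 1L + stats::rnbinom(s, mu = 4, size = 0.8)
  }
  comm
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator in sequence: phylogeny, soil grid, patch
#' delineation and geometry, quadrat samples, and communities.
#'
#' @param config A [synth_config()].
#' @param connectivity Patch adjacency rule, 4 (default) or 8.
#' @return List: `config`, `tree`, `grid`, `patch_map`, `patches`
#'   (geometry table), `samples`, `comm`.
#' @export
simulate_dataset <- function(config = synth_config(), connectivity = 4) {
  tree <- gen_tree(config$n_taxa, config$seed)
  grid <- gen_soil_grid(config)
  pm <- delineate_patches(grid, connectivity)
  if (pm$n_patches == 0L) stop("configuration produced an all-rock grid")
  patches <- patch_metrics(pm)
  samples <- gen_resource_samples(pm, config, seed = config$seed + 1L)
  comm <- gen_communities(patches, tree, config, seed = config$seed + 2L)
  list(config = config, tree = tree, grid = grid, patch_map = pm,
       patches = patches, samples = samples, comm = comm)
}
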