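#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the chosen columns of a
#' patch table, with two-sided p-values and, as a clearly-labelled
#' extension, Holm-adjusted p-values. Pairs with fewer than 3 complete rows
#' or a constant column are `NA`.
#'
#' @param table data.frame, one row per patch.
#' @param variables Column names to correlate (default: all numeric
#'   columns).
#' @return List of matrices `r`, `p`, `p_holm`, `n` (complete pairs).
#' @export
pearson_matrix <- function(table, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  miss <- setdiff(variables, names(table))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  m <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, m, m,
                           dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      x <- table[[variables[i]]]; y <- table[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  p_holm <- p
  low <- lower.tri(p)
  p_holm[low] <- stats::p.adjust(p[low], method = "holm")
  p_holm[upper.tri(p_holm)] <- t(p_holm)[upper.tri(p_holm)]
  list(r = r, p = p, p_holm = p_holm, n = nmat)
}

#' Log-linear diversity-area fit
#'
#' Ordinary least squares of a diversity metric on `log10(PA)` — the
#' species-area form used to relate richness, Shannon diversity or PD to
#' soil patch area.
#'
#' @param PA Patch areas in m2 (> 0).
#' @param y Metric values, same length; non-finite pairs are dropped.
#' @return List: `slope` (units of y per decade of area), `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `n`.
#' @export
fit_loglinear <- function(PA, y) {
  if (length(PA) != length(y)) stop("'PA' and 'y' lengths differ")
  if (any(PA <= 0, na.rm = TRUE)) stop("'PA' must be positive")
  ok <- is.finite(PA) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 complete points")
  x <- log10(PA[ok]); yy <- y[ok]
  if (stats::sd(x) == 0) stop("degenerate design: PA is constant")
  if (stats::sd(yy) == 0) {
    # constant response: flat fit, no variance to explain
    return(list(slope = 0, intercept = yy[1], r_squared = 0,
                p_value = NA_real_, n = sum(ok)))
  }
  fit <- stats::lm(yy ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = sum(ok))
}

#' Assemble the per-patch analysis table
#'
#' Joins patch geometry, soil resources, taxonomic diversity, Faith's PD
#' and phylogenetic structure on `patch_id`. Missing metrics stay `NaN`;
#' inconsistent patch ids across inputs are an error naming the orphans.
#'
#' @param patches Geometry table from [patch_metrics()].
#' @param resources Table from [patch_resources()] (optional).
#' @param diversity Table from [taxonomic_diversity()] (optional).
#' @param pd Table from [community_pd()] (optional).
#' @param structure Table from [phylo_structure()] (optional).
#' @return data.frame keyed by `patch_id`.
#' @export
patch_table <- function(patches, resources = NULL, diversity = NULL,
                        pd = NULL, structure = NULL) {
  tab <- patches
  tab$patch_id <- as.character(tab$patch_id)
  for (piece in list(resources, diversity, pd, structure)) {
    if (is.null(piece)) next
    piece$patch_id <- as.character(piece$patch_id)
    orphans <- setdiff(piece$patch_id, tab$patch_id)
    if (length(orphans)) {
      stop("patch id(s) absent from the geometry table: ",
           paste(orphans, collapse = ", "))
    }
    tab <- merge(tab, piece, by = "patch_id", all.x = TRUE, sort = FALSE)
  }
  tab[order(as.numeric(tab$patch_id)), , drop = FALSE]
}

#' Build the full patch-scale report
#'
#' Runs the whole pipeline on its inputs and writes, under `out_dir`:
#' `patch_table.csv` (one row per patch), `summary_properties.csv` and
#' `summary_diversity.csv` (min/max/mean/SD/CV rows), `correlations_r.csv`
#' and `correlations_p.csv`, `fits.csv` (diversity ~ log10 area), and
#' `manifest.json` (seed, parameters, package version, timestamp).
#'
#' @param grid A [soil_grid()].
#' @param samples Quadrat sample table (see [patch_resources()]).
#' @param comm Community matrix (patches x species); rownames must match
#'   patch ids from delineation.
#' @param tree Rooted `phylo` covering the community's species.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param connectivity Patch adjacency, 4 or 8.
#' @param n_perm Null permutations for NRI/NTI.
#' @param seed Integer seed for the null models.
#' @return Invisibly, a list with `table`, `summaries`, `correlations`,
#'   `fits`, `manifest`.
#' @export
build_report <- function(grid, samples, comm, tree, out_dir = NULL,
                         connectivity = 4, n_perm = 999, seed = 1L) {
  pm <- delineate_patches(grid, connectivity)
  patches <- patch_metrics(pm)
  res <- patch_resources(samples)
  div <- taxonomic_diversity(comm)
  pd <- community_pd(comm, tree)
  struct <- phylo_structure(comm, tree, n_perm = n_perm, seed = seed)
  struct$R <- NULL  # already carried by the diversity table
  tab <- patch_table(patches, res, div, pd, struct)

  # a variable with < 2 finite values (e.g. NTI on a one-patch plot) gets
  # an all-NA summary row rather than aborting the report
  safe_summary <- function(v) {
    row <- tryCatch(summarize_patch_properties(tab[[v]]),
                    error = function(e) {
                      data.frame(min = NA_real_, max = NA_real_,
                                 mean = NA_real_, SD = NA_real_,
                                 CV = NA_real_,
                                 n = sum(is.finite(tab[[v]])),
                                 n_excluded = sum(!is.finite(tab[[v]])))
                    })
    cbind(variable = v, row)
  }
  sum_props <- do.call(rbind, lapply(c("PA_m2", "PM_m", "PFD"), safe_summary))
  div_vars <- c("R", "H", "E", "PD", "NRI", "NTI")
  sum_div <- do.call(rbind, lapply(div_vars, safe_summary))

  cor_vars <- intersect(c("PA_m2", "PM_m", "PFD", "PA_ratio",
                          paste0(resource_vars, "_mean"),
                          paste0(resource_vars, "_cv"), div_vars),
                        names(tab))
  cors <- pearson_matrix(tab, cor_vars)

  fits <- do.call(rbind, lapply(div_vars, function(v) {
    f <- tryCatch(fit_loglinear(tab$PA_m2, tab[[v]]), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(metric = v, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, p_value = f$p_value, n = f$n)
  }))

  manifest <- list(seed = seed, n_perm = n_perm, connectivity = connectivity,
                   n_patches = pm$n_patches,
                   cell_side = grid$cell_side,
                   package_version = as.character(
                     utils::packageVersion("karstpatch")),
                   timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "patch_table.csv"),
                     row.names = FALSE)
    utils::write.csv(sum_props, file.path(out_dir, "summary_properties.csv"),
                     row.names = FALSE)
    utils::write.csv(sum_div, file.path(out_dir, "summary_diversity.csv"),
                     row.names = FALSE)
    utils::write.csv(cors$r, file.path(out_dir, "correlations_r.csv"))
    utils::write.csv(cors$p, file.path(out_dir, "correlations_p.csv"))
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(table = tab,
                 summaries = list(properties = sum_props, diversity = sum_div),
                 correlations = cors, fits = fits, manifest = manifest))
}
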