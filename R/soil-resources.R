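#' @keywords internal
resource_vars <- c("Sd_cm", "SWC_pct", "TC_gkg", "TN_gkg", "TCTN")

validate_sample_table <- function(samples) {
  need <- c("patch_id", "Sd_cm", "SWC_pct", "TC_gkg", "TN_gkg")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)
  if (!"TCTN" %in% names(samples)) {
    # carbon-to-nitrogen ratio is a per-record variable
    samples$TCTN <- ifelse(samples$TN_gkg > 0,
                           samples$TC_gkg / samples$TN_gkg, NaN)
  }
  samples
}

patch_records <- function(samples, patch_id) {
  rec <- samples[samples$patch_id == patch_id, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for patch ", patch_id)
  rec
}

#' Per-patch resource availability (means)
#'
#' Arithmetic mean of each soil variable over a patch's quadrat records:
#' soil depth (Sd, cm), water content (SWC, %), total carbon (TC, g/kg),
#' total nitrogen (TN, g/kg), and the per-record carbon-to-nitrogen ratio
#' (TC/TN). Depth means use only records with Sd > 0, since depth is
#' measured only where soil is present.
#'
#' @param samples Sample table with columns `patch_id`, `Sd_cm`, `SWC_pct`,
#'   `TC_gkg`, `TN_gkg`.
#' @param patch_id Patch to summarize.
#' @return Named numeric vector of means for `Sd_cm`, `SWC_pct`, `TC_gkg`,
#'   `TN_gkg`, `TCTN`.
#' @export
availability_mean <- function(samples, patch_id) {
  samples <- validate_sample_table(samples)
  rec <- patch_records(samples, patch_id)
  out <- vapply(resource_vars, function(v) {
    x <- rec[[v]]
    if (v == "Sd_cm") x <- x[x > 0]
    if (length(x) == 0L) NaN else mean(x)
  }, numeric(1))
  out
}

#' Per-patch resource heterogeneity (coefficient of variation)
#'
#' CV = sample SD / mean for each soil variable over a patch's quadrat
#' records. Depth CVs use only records with Sd > 0. A single record or a
#' zero mean yields `NaN`.
#'
#' @inheritParams availability_mean
#' @param population_sd Use the n-denominator SD instead of the sample SD.
#' @return Named numeric vector of CVs (dimensionless).
#' @examples
#' tab <- data.frame(patch_id = 1, Sd_cm = c(10, 20), SWC_pct = c(15, 15),
#'                   TC_gkg = c(2, 2), TN_gkg = c(0.2, 0.2))
#' heterogeneity_cv(tab, 1)[["Sd_cm"]]  # 0.4714
#' @export
heterogeneity_cv <- function(samples, patch_id, population_sd = FALSE) {
  samples <- validate_sample_table(samples)
  rec <- patch_records(samples, patch_id)
  vapply(resource_vars, function(v) {
    x <- rec[[v]]
    if (v == "Sd_cm") x <- x[x > 0]
    if (length(x) < 2L) return(NaN)
    m <- mean(x)
    if (m == 0) return(NaN)
    s <- stats::sd(x)
    if (population_sd) s <- s * sqrt((length(x) - 1) / length(x))
    s / m
  }, numeric(1))
}

#' Classify variability strength from a CV
#'
#' Standard soil-science variability classes: strong (CV >= 0.36),
#' moderate, weak (CV <= 0.15). The printed class limits (<=15%, 16%-35%,
#' >=36%) leave (0.15, 0.16) and (0.35, 0.36) uncovered; they are resolved
#' by closing the classes on the printed endpoints, so moderate is
#' (0.15, 0.36).
#'
#' @param cv Non-negative coefficient(s) of variation.
#' @return Character vector in `{"weak", "moderate", "strong"}`; `NA` for
#'   non-finite input.
#' @examples
#' classify_cv(c(0.53, 0.18, 0.07))  # strong, moderate, weak
#' @export
classify_cv <- function(cv) {
  if (any(is.finite(cv) & cv < 0)) stop("'cv' must be non-negative")
  ifelse(!is.finite(cv), NA_character_,
         ifelse(cv >= 0.36, "strong",
                ifelse(cv <= 0.15, "weak", "moderate")))
}

#' Per-patch resource availability and heterogeneity table
#'
#' Applies [availability_mean()] and [heterogeneity_cv()] to every patch in
#' a sample table and attaches variability classes.
#'
#' @inheritParams heterogeneity_cv
#' @return A data.frame with one row per patch: `patch_id`, `<var>_mean`,
#'   `<var>_cv`, `<var>_class` for each of Sd, SWC, TC, TN, TC/TN.
#' @export
patch_resources <- function(samples, population_sd = FALSE) {
  samples <- validate_sample_table(samples)
  ids <- sort(unique(samples$patch_id))
  rows <- lapply(ids, function(id) {
    m <- availability_mean(samples, id)
    cv <- heterogeneity_cv(samples, id, population_sd = population_sd)
    out <- c(list(patch_id = id), as.list(m), as.list(cv))
    names(out) <- c("patch_id", paste0(resource_vars, "_mean"),
                    paste0(resource_vars, "_cv"))
    as.data.frame(out)
  })
  res <- do.call(rbind, rows)
  for (v in resource_vars) {
    res[[paste0(v, "_class")]] <- classify_cv(res[[paste0(v, "_cv")]])
  }
  res
}
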