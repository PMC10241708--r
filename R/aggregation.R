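#' Aggregate core-level results into case-level metrics
#'
#' TMA cases are represented by replicate cores; in `"pooled"` mode (the
#' default) the cores of one case are treated as one entire tissue sample:
#' vessel tables are concatenated and areas summed before density, median
#' diameter, PVI and FCV are computed. In `"median_of_cores"` mode each
#' metric is computed per core and combined by the median. Cores that failed
#' quality control are dropped; a case with no passing core is flagged
#' `qc_excluded` with all metrics NA.
#'
#' @param core_results list of per-core results as returned by
#'   [measure_image()] (each needs `$metrics` and `$per_vessel`).
#' @param mode `"pooled"` or `"median_of_cores"`.
#' @param qc_pass logical vector, one flag per core (default all pass).
#' @param case_id identifier copied to the output.
#' @param fcv_cutoff optional covered/uncovered cutoff used to (re)compute
#'   FCV from the pooled per-vessel perivascular ODs.
#' @return one-row data frame of class `case_metrics`: case_id, n_cores_used,
#'   qc_excluded, n_vessels, vessel_density, vessel_median_diameter_um, pvi,
#'   fcv, stromal_area_mm2, stromal_sma_od_median, tissue_area_mm2,
#'   aggregation mode; attribute `per_vessel` holds the pooled vessel table.
#' @export
aggregate_case <- function(core_results, mode = c("pooled", "median_of_cores"),
                           qc_pass = rep(TRUE, length(core_results)),
                           case_id = "case", fcv_cutoff = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(qc_pass) == length(core_results))
  core_results <- core_results[qc_pass]
  if (length(core_results) == 0L) {
    out <- data.frame(case_id = case_id, n_cores_used = 0L, qc_excluded = TRUE,
                      n_vessels = NA_integer_, vessel_density = NA_real_,
                      vessel_median_diameter_um = NA_real_, pvi = NA_real_,
                      fcv = NA_real_, stromal_area_mm2 = NA_real_,
                      stromal_sma_od_median = NA_real_,
                      tissue_area_mm2 = NA_real_, mode = mode)
    class(out) <- c("case_metrics", "data.frame")
    return(out)
  }
  mets <- do.call(rbind, lapply(core_results, `[[`, "metrics"))
  pv <- do.call(rbind, lapply(seq_along(core_results), function(i) {
    t <- core_results[[i]]$per_vessel
    if (nrow(t)) cbind(core = i, t) else NULL
  }))
  if (is.null(pv)) pv <- data.frame(core = integer(0), label = integer(0),
                                    min_feret_um = numeric(0),
                                    pv_od_median = numeric(0))
  total_area <- sum(mets$tissue_area_mm2)
  n_vessels <- nrow(pv)
  if (mode == "pooled") {
    dens <- n_vessels / total_area
    mdiam <- if (n_vessels) stats::median(pv$min_feret_um) else NA_real_
    pvi <- if (n_vessels) stats::median(pv$pv_od_median, na.rm = TRUE) else NA_real_
    fcv <- if (!is.null(fcv_cutoff)) fraction_covered(pv$pv_od_median, fcv_cutoff)
           else stats::median(mets$fcv)
    strom_area <- sum(mets$stromal_area_mm2)
    strom_od <- stats::median(mets$stromal_od, na.rm = TRUE)
  } else {
    dens <- stats::median(mets$density)
    mdiam <- stats::median(mets$median_diameter_um, na.rm = TRUE)
    pvi <- stats::median(mets$pvi, na.rm = TRUE)
    fcv <- if (!is.null(fcv_cutoff))
      stats::median(vapply(core_results, function(cr)
        fraction_covered(cr$per_vessel$pv_od_median, fcv_cutoff), numeric(1)),
        na.rm = TRUE)
      else stats::median(mets$fcv, na.rm = TRUE)
    strom_area <- stats::median(mets$stromal_area_mm2)
    strom_od <- stats::median(mets$stromal_od, na.rm = TRUE)
  }
  out <- data.frame(case_id = case_id, n_cores_used = length(core_results),
                    qc_excluded = FALSE, n_vessels = n_vessels,
                    vessel_density = dens, vessel_median_diameter_um = mdiam,
                    pvi = pvi, fcv = fcv, stromal_area_mm2 = strom_area,
                    stromal_sma_od_median = strom_od,
                    tissue_area_mm2 = total_area, mode = mode)
  attr(out, "per_vessel") <- pv
  class(out) <- c("case_metrics", "data.frame")
  out
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Concordance of replicate-core measurements: the proportion of total
#' variance attributable to between-case differences,
#' sigma_b^2 / (sigma_b^2 + sigma_w^2), estimated from the one-way ANOVA
#' mean squares with unbalanced-design formulas; the 95% CI comes from the
#' F distribution of MSB/MSW.
#'
#' @param values numeric vector of core-level measurements.
#' @param case factor/vector identifying the case of each measurement.
#' @param conf_level confidence level (default 0.95).
#' @return list: `estimate`, `ci_low`, `ci_high`, `n_cases`, `n_cores`
#'   (total observations), `k0` (effective cores per case).
#' @export
compute_icc <- function(values, case, conf_level = 0.95) {
  ok <- !is.na(values) & !is.na(case)
  values <- values[ok]; case <- factor(case[ok])
  ki <- table(case)
  if (length(ki) < 2L) stop("need >= 2 cases")
  if (all(ki < 2L)) stop("all cases single-core: within-case variance undefined")
  N <- sum(ki); n <- length(ki)
  gm <- mean(values)
  mi <- tapply(values, case, mean)
  ssb <- sum(ki * (mi - gm)^2)
  ssw <- sum((values - mi[case])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(ki^2) / N) / (n - 1)   # Searle's unbalanced replicate count
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  alpha <- 1 - conf_level
  Fobs <- msb / msw
  fl <- Fobs / stats::qf(1 - alpha / 2, n - 1, N - n)
  fu <- Fobs * stats::qf(1 - alpha / 2, N - n, n - 1)
  list(estimate = icc,
       ci_low = (fl - 1) / (fl + k0 - 1),
       ci_high = (fu - 1) / (fu + k0 - 1),
       n_cases = n, n_cores = as.integer(N), k0 = k0)
}
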