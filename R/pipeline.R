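#' Default run configuration
#'
#' Returns the full default configuration for [run_pipeline()], which can be
#' edited or written to YAML. All radii are in pixels at the stated
#' resolution (paper convention: 4 px/um); the seed is mandatory and governs
#' every random draw of the run.
#'
#' @param seed integer seed.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    resolution_px_per_um = 4,
    stains = list(CD34 = c(0.21393921, 0.85112669, 0.47794022),
                  aSMA = c(0.74890292, 0.60624161, 0.26731082)),
    synthesis = list(
      enabled = TRUE,
      n_cases = 20L, cores_per_case = 3L,
      image_size_px = c(384L, 384L),
      n_vessels_per_core = 6L,
      diameter_log_sd = 0.25,
      true_log_hr = log(3), baseline_hazard = 0.004, censoring_rate = 0.3,
      noise_sd_od = 0.02,
      n_distractors = 8L,
      write_images = FALSE),
    input = list(images_csv = NULL, clinical_csv = NULL),
    segmentation = list(threshold = "otsu", od_max = 2,
                        despeckle_radius_px = 2L, enlarge_radius_px = 3L,
                        smooth_radius_px = 2L, min_feret_floor_um = 4),
    morphometry = list(ring_distance_px = 10L, stroma_threshold_od = 0.15),
    aggregation = list(mode = "pooled", fcv_cutoff = "cohort_median"),
    statistics = list(ties = "breslow", dichotomize_metric = "vessel_median_diameter_um"),
    output_dir = "vesselquant_run"),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_run_config()]; the seed must be
#' present in the file.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config error: seed is mandatory in the config file")
  base <- default_run_config(cfg$seed)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_cfg(unclass(base), cfg), class = "run_config")
}

# deterministic sub-seed; double arithmetic avoids integer overflow and the
# modulus keeps the result below 2^31
sub_seed <- function(seed, i, j = 0L)
  as.integer((as.numeric(seed) * 7 + i * 1009 + j * 101) %% 2000000011)

#' Run the full pipeline
#'
#' Orchestrates synthesize (or load) -> stain separation -> segmentation ->
#' morphometry -> case aggregation -> cohort statistics, writing per-vessel,
#' per-image and per-case CSVs, a statistics JSON and a run manifest into
#' `config$output_dir`. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `per_image`, `per_case`, `cohort`, `stats`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  cfg <- unclass(config)
  if (is.null(cfg$seed)) stop("config error: seed missing")
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stains <- stain_model(cfg$stains, names = names(cfg$stains))
  res <- cfg$resolution_px_per_um

  if (isTRUE(cfg$synthesis$enabled)) {
    sy <- cfg$synthesis
    cohort <- generate_cohort(sy$n_cases, true_log_hr = sy$true_log_hr,
                              baseline_hazard = sy$baseline_hazard,
                              censoring_rate = sy$censoring_rate,
                              seed = sub_seed(cfg$seed, 0L))
    say("synthesized cohort of ", nrow(cohort), " cases")
    images <- list(); truth_all <- list()
    for (i in seq_len(nrow(cohort))) {
      # per-case vessel calibre tracks the cohort's true size: target outer
      # median diameter = size_um, mean wall 2.25 um
      lumen_med <- max(4.2, cohort$size_um[i] - 4.5)
      for (j in seq_len(sy$cores_per_case)) {
        # rejection sampling over sub-seeds, shedding vessels if a
        # large-calibre case cannot fit the full count on one core (large
        # vessels <-> fewer per field, as in real tissue); deterministic
        lay <- NULL
        for (attempt in 0:11) {
          n_eff <- max(1L, sy$n_vessels_per_core - max(0L, attempt - 3L))
          lay <- tryCatch(generate_vessel_layout(
            n_eff, diameter_log_mean = log(lumen_med),
            diameter_log_sd = sy$diameter_log_sd,
            image_size_px = sy$image_size_px, resolution_px_per_um = res,
            n_distractors = sy$n_distractors,
            seed = (sub_seed(cfg$seed, i, j) + attempt * 7919L) %% 2000000011L),
            error = function(e) NULL)
          if (!is.null(lay)) break
        }
        if (is.null(lay))
          stop("data error: synthesis could not place ", sy$n_vessels_per_core,
               " vessels of case calibre ", round(lumen_med, 1),
               " um on a ", sy$image_size_px[1], "x", sy$image_size_px[2],
               " px core")
        ren <- render_ihc_image(lay, stains, noise_sd_od = sy$noise_sd_od,
                                seed = sub_seed(cfg$seed, i, j) + 1L)
        id <- sprintf("%s_core%d", cohort$case_id[i], j)
        if (isTRUE(sy$write_images))
          write_ihc_image(ren, file.path(out_dir, paste0(id, ".tiff")))
        images[[id]] <- list(image = ren$image, case_id = cohort$case_id[i],
                             core_id = j)
        tr <- ren$truth
        if (nrow(tr)) truth_all[[id]] <- cbind(case_id = cohort$case_id[i],
                                               core_id = j, tr)
      }
    }
    truth <- if (length(truth_all)) do.call(rbind, truth_all) else NULL
    if (!is.null(truth))
      utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    clinical <- cohort
  } else {
    inp <- cfg$input
    if (is.null(inp$images_csv)) stop("data error: no inputs (set synthesis$enabled or input$images_csv)")
    man <- utils::read.csv(inp$images_csv, stringsAsFactors = FALSE)
    if (nrow(man) == 0L) stop("data error: no inputs listed in images_csv")
    need <- c("image_path", "case_id", "core_id")
    if (!all(need %in% names(man)))
      stop("data error: images_csv needs columns ", paste(need, collapse = ", "))
    images <- list()
    for (i in seq_len(nrow(man))) {
      id <- sprintf("%s_core%s", man$case_id[i], man$core_id[i])
      images[[id]] <- list(image = read_ihc_image(man$image_path[i], res),
                           case_id = man$case_id[i], core_id = man$core_id[i])
    }
    clinical <- if (!is.null(inp$clinical_csv))
      utils::read.csv(inp$clinical_csv, stringsAsFactors = FALSE) else NULL
    truth <- NULL
  }

  sg <- cfg$segmentation; mo <- cfg$morphometry
  per_image <- list(); measured <- list()
  for (id in names(images)) {
    m <- measure_image(images[[id]]$image, stains = stains,
                       threshold = sg$threshold, od_max = sg$od_max,
                       despeckle_radius_px = sg$despeckle_radius_px,
                       enlarge_radius_px = sg$enlarge_radius_px,
                       smooth_radius_px = sg$smooth_radius_px,
                       min_feret_floor_um = sg$min_feret_floor_um,
                       ring_distance_px = mo$ring_distance_px,
                       stroma_threshold_od = mo$stroma_threshold_od,
                       resolution_px_per_um = res)
    measured[[id]] <- m
    per_image[[id]] <- cbind(image_id = id, case_id = images[[id]]$case_id,
                             core_id = images[[id]]$core_id, m$metrics)
    say("measured ", id, ": ", m$metrics$n_vessels, " vessels")
  }
  per_image_df <- do.call(rbind, per_image)

  # cohort-level FCV cutoff: median of per-vessel perivascular OD
  all_pv <- unlist(lapply(measured, function(m) m$per_vessel$pv_od_median))
  fcv_cutoff <- if (identical(cfg$aggregation$fcv_cutoff, "cohort_median"))
    stats::median(all_pv, na.rm = TRUE) else as.numeric(cfg$aggregation$fcv_cutoff)

  case_ids <- unique(vapply(images, `[[`, "", "case_id"))
  per_case <- do.call(rbind, lapply(case_ids, function(cid) {
    sel <- vapply(images, function(x) identical(x$case_id, cid), logical(1))
    aggregate_case(measured[sel], mode = cfg$aggregation$mode,
                   case_id = cid, fcv_cutoff = fcv_cutoff)
  }))

  per_vessel_df <- do.call(rbind, lapply(names(measured), function(id) {
    t <- measured[[id]]$per_vessel
    if (nrow(t)) cbind(image_id = id, case_id = images[[id]]$case_id, t) else NULL
  }))

  utils::write.csv(per_image_df, file.path(out_dir, "per_image.csv"), row.names = FALSE)
  utils::write.csv(per_case, file.path(out_dir, "per_case.csv"), row.names = FALSE)
  if (!is.null(per_vessel_df))
    utils::write.csv(per_vessel_df, file.path(out_dir, "per_vessel.csv"),
                     row.names = FALSE)

  stats_out <- list(fcv_cutoff = fcv_cutoff)
  if (!is.null(clinical)) {
    tab <- merge(per_case, as.data.frame(clinical), by = "case_id")
    metric <- cfg$statistics$dichotomize_metric
    if (!metric %in% names(tab)) stop("data error: metric ", metric, " absent")
    tab$metric_group <- dichotomize(tab[[metric]])
    utils::write.csv(tab[order(tab$case_id), ],
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    if (sum(tab$event, na.rm = TRUE) >= 1L &&
        length(unique(stats::na.omit(tab$metric_group))) == 2L) {
      kl <- km_logrank(tab$time, tab$event, tab$metric_group)
      uni <- tryCatch(cox_fit(tab$time, tab$event,
                              data.frame(metric_group = tab$metric_group),
                              ties = cfg$statistics$ties),
                      error = function(e) NULL)
      stats_out$logrank <- list(chisq = kl$chisq, p = kl$p, n = kl$n,
                                n_events = kl$n_events)
      if (!is.null(uni))
        stats_out$cox_univariable <- uni$table
      km_df <- with(summary(kl$fit),
                    data.frame(group = as.character(strata), time = time,
                               n_risk = n.risk, n_event = n.event, surv = surv))
      utils::write.csv(km_df, file.path(out_dir, "km_curves.csv"), row.names = FALSE)
    } else say("statistics not estimable: too few events or one group")
  } else {
    tab <- per_case
    utils::write.csv(tab[order(tab$case_id), ],
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # output_dir is where results land, not part of the scientific
  # configuration: excluding it keeps manifests of identical runs identical
  manifest <- list(package = "vesselquant",
                   version = as.character(utils::packageVersion("vesselquant")),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "output_dir")])
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("wrote outputs to ", out_dir)
  invisible(list(per_image = per_image_df, per_case = per_case,
                 cohort = if (exists("tab")) tab else NULL,
                 stats = stats_out, output_dir = out_dir))
}
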