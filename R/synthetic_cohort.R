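#' Simulate a breast-cancer-like cohort with known hazard structure
#'
#' Per-case vessel median size is drawn log-normal; cases above the cohort
#' median form the "high" group, whose event hazard is multiplied by
#' `exp(true_log_hr)` under an exponential baseline (the simplest
#' proportional-hazards-consistent generator, with closed-form truth).
#' Independent exponential censoring is calibrated numerically so the
#' expected censoring fraction equals `censoring_rate`. Clinical covariates
#' (age, tumour size, grade, nodal status, receptor status, subtype) are
#' drawn with screening-cohort-like frequencies, independent of vessel size
#' by default.
#'
#' @param n_cases number of cases (>= 2).
#' @param true_log_hr log hazard ratio of the high-vessel-size group.
#' @param baseline_hazard events per month in the low group (default 0.004,
#'   i.e. median survival of roughly 14 years, consistent with a
#'   screening-detected cohort).
#' @param censoring_rate target fraction of censored cases in `[0, 1)`.
#' @param size_log_mean,size_log_sd meanlog / sdlog of per-case vessel median
#'   size (um).
#' @param seed integer seed.
#' @return A `vq_cohort` data frame: case_id, size_um, group, time (months),
#'   event (0/1), covariates; attributes `true_log_hr`, `censoring_rate`,
#'   `seed`.
#' @export
generate_cohort <- function(n_cases, true_log_hr = 0, baseline_hazard = 0.004,
                            censoring_rate = 0.3,
                            size_log_mean = log(12), size_log_sd = 0.35,
                            seed) {
  stopifnot(n_cases >= 2, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  size <- stats::rlnorm(n_cases, size_log_mean, size_log_sd)
  high <- size > stats::median(size)
  lam <- baseline_hazard * exp(true_log_hr * high)
  t_event <- stats::rexp(n_cases, lam)
  if (censoring_rate > 0) {
    # P(C < T | case i) = hc / (hc + lam_i) for independent exponentials
    f <- function(hc) mean(hc / (hc + lam)) - censoring_rate
    hc <- stats::uniroot(f, c(1e-10, 1e6))$root
    t_cens <- stats::rexp(n_cases, hc)
  } else t_cens <- rep(Inf, n_cases)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  covar <- data.frame(
    age_group = factor(ifelse(stats::runif(n_cases) < 0.5, "<=60", ">60"),
                       levels = c("<=60", ">60")),
    tumor_size_group = factor(ifelse(stats::runif(n_cases) < 0.65,
                                     "<=20mm", ">20mm"),
                              levels = c("<=20mm", ">20mm")),
    grade = factor(sample(c("G1", "G2", "G3"), n_cases, TRUE,
                          prob = c(0.2, 0.45, 0.35)), levels = c("G1", "G2", "G3")),
    nodal_status = factor(sample(c("N0", "N1"), n_cases, TRUE,
                                 prob = c(0.7, 0.3)), levels = c("N0", "N1")),
    er_status = factor(sample(c("pos", "neg"), n_cases, TRUE,
                              prob = c(0.85, 0.15)), levels = c("pos", "neg")),
    pr_status = factor(sample(c("pos", "neg"), n_cases, TRUE,
                              prob = c(0.75, 0.25)), levels = c("pos", "neg")),
    her2_status = factor(sample(c("neg", "pos"), n_cases, TRUE,
                                prob = c(0.88, 0.12)), levels = c("neg", "pos")))

  out <- data.frame(case_id = sprintf("case_%04d", seq_len(n_cases)),
                    size_um = size,
                    group = factor(ifelse(high, "high", "low"),
                                   levels = c("low", "high")),
                    time = time, event = event, covar)
  attr(out, "true_log_hr") <- true_log_hr
  attr(out, "censoring_rate") <- censoring_rate
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("vq_cohort", "data.frame")
  out
}
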