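#' Dichotomize a continuous metric at the cohort median
#'
#' Cases at or below the cohort median form the "low (0-50%)" group, cases
#' strictly above it the "high (> 50%)" group; ties at the median go low.
#' Missing values stay missing.
#'
#' @param values numeric vector.
#' @return factor with levels `low`, `high` and attribute `cutoff` (the
#'   median used).
#' @export
dichotomize <- function(values) {
  if (all(is.na(values))) stop("all values missing")
  if (sum(!is.na(values)) < 2L) stop("need >= 2 non-missing values")
  cutoff <- stats::median(values, na.rm = TRUE)
  g <- factor(ifelse(values <= cutoff, "low", "high"), levels = c("low", "high"))
  attr(g, "cutoff") <- cutoff
  g
}

#' Spearman rank correlation with two-tailed p
#'
#' Rank correlation with midrank ties. For n <= 10 without ties the p value
#' comes from the exact null distribution of the rank statistic; otherwise
#' from the t approximation on rho.
#'
#' @param x,y paired numeric vectors, >= 4 complete pairs.
#' @return list `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  rho <- stats::cor(rank(x), rank(y))
  if (n <= 10L && !ties) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = n, method = "exact")
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    list(rho = rho, p = min(1, p), n = n, method = "t-approximation")
  }
}

#' Rank-based group comparison
#'
#' Mann-Whitney (Wilcoxon rank-sum) for two groups, Kruskal-Wallis for more,
#' both tie-corrected and two-sided.
#'
#' @param values numeric vector.
#' @param groups grouping factor/vector.
#' @return list `p`, `statistic`, `test`, `n_groups`.
#' @export
group_tests <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 non-empty groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (nlevels(groups) == 2L) {
    ht <- suppressWarnings(stats::wilcox.test(values ~ groups))
    list(p = ht$p.value, statistic = unname(ht$statistic),
         test = "mann-whitney", n_groups = 2L)
  } else {
    ht <- stats::kruskal.test(values ~ groups)
    list(p = ht$p.value, statistic = unname(ht$statistic),
         test = "kruskal-wallis", n_groups = nlevels(groups))
  }
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per group and the log-rank test of the
#' observed-vs-expected event counts over the pooled event times.
#'
#' @param time positive survival times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group grouping factor.
#' @return list `fit` (a [survival::survfit] object), `chisq`, `df`, `p`,
#'   `n`, `n_events`; `chisq`/`p` are NA (with warning) when no events.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(all(time > 0, na.rm = TRUE))
  group <- factor(group)
  if (any(table(group) == 0L)) stop("empty group")
  df_in <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df_in)
  if (sum(event, na.rm = TRUE) == 0L) {
    warning("no events: log-rank test undefined")
    return(list(fit = fit, chisq = NA_real_, df = NA_integer_, p = NA_real_,
                n = nrow(df_in), n_events = 0L))
  }
  if (nlevels(droplevels(group)) < 2L)
    return(list(fit = fit, chisq = NA_real_, df = 0L, p = NA_real_,
                n = nrow(df_in), n_events = sum(event, na.rm = TRUE)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df_in)
  df_ <- length(sd_$n) - 1L
  list(fit = fit, chisq = sd_$chisq, df = df_,
       p = stats::pchisq(sd_$chisq, df_, lower.tail = FALSE),
       n = nrow(df_in), n_events = sum(event, na.rm = TRUE))
}

#' Cause-specific Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation via [survival::coxph] with Breslow tie
#' handling by default (Efron selectable). Reports per-term hazard ratios,
#' Wald 95% CIs and p values. Non-convergence or monotone likelihood
#' (complete separation, seen as exploding coefficients) raises an explicit
#' error rather than returning a silent result.
#'
#' @param time,event survival times and event indicators.
#' @param covariates data frame of covariates (factors coded with their
#'   reference level first), or a single vector.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `survival_result`: list with `table` (data frame:
#'   term, coef, HR, ci_low, ci_high, se, p), `n`, `n_events`, `ties`,
#'   `model` (the coxph fit).
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(event, na.rm = TRUE) < 1L) stop("no events: Cox model not estimable")
  if (!is.data.frame(covariates)) covariates <- data.frame(x = covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite|coefficient may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        stop("Cox fit did not converge (possible monotone likelihood / complete separation): ",
             conditionMessage(w), call. = FALSE)
      suppressWarnings(survival::coxph(fml, data = dat, ties = ties,
                                       control = survival::coxph.control(eps = 1e-9,
                                                                         iter.max = 50)))
    })
  s <- summary(fit)
  co <- s$coefficients
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                    HR = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    se = co[, "se(coef)"], p = co[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, n = s$n, n_events = sum(dat$.event),
                 ties = ties, model = fit),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(transform(x$table, HR = round(HR, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3), p = signif(p, 3),
                  coef = round(coef, 4), se = round(se, 4)))
  invisible(x)
}

#' Univariable Cox fits across clinicopathologic subgroups
#'
#' For each subgroup (a logical selection of cases) the dichotomized
#' exposure's univariable hazard ratio is fitted; subgroups with fewer than
#' `min_cases` cases, fewer than `min_events` events, or only one exposure
#' level are reported as not estimable instead of fitted — the rows of a
#' forest plot.
#'
#' @param data data frame with `time`, `event` columns and the exposure.
#' @param exposure name of the dichotomized exposure column (factor).
#' @param subgroups named list of logical vectors (or NULL for the whole
#'   cohort only).
#' @param min_cases,min_events estimability thresholds (defaults 2 and 1).
#' @return data frame: subgroup, n, n_events, HR, ci_low, ci_high, p,
#'   estimable.
#' @export
subgroup_forest <- function(data, exposure, subgroups = NULL,
                            min_cases = 2L, min_events = 1L) {
  stopifnot(all(c("time", "event", exposure) %in% names(data)))
  if (is.null(subgroups)) subgroups <- list(all = rep(TRUE, nrow(data)))
  rows <- lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]] & !is.na(data[[exposure]])
    d <- data[sel, , drop = FALSE]
    ne <- sum(d$event, na.rm = TRUE)
    base <- data.frame(subgroup = nm, n = nrow(d), n_events = ne,
                       HR = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p = NA_real_, estimable = FALSE)
    if (nrow(d) < min_cases || ne < min_events ||
        length(unique(stats::na.omit(d[[exposure]]))) < 2L) return(base)
    res <- tryCatch(cox_fit(d$time, d$event, d[exposure]),
                    error = function(e) NULL)
    if (is.null(res)) return(base)
    base[c("HR", "ci_low", "ci_high", "p")] <-
      res$table[1, c("HR", "ci_low", "ci_high", "p")]
    base$estimable <- TRUE
    base
  })
  do.call(rbind, rows)
}
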