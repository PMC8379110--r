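# Cohort-level statistics: completeness tables, association tests,
# LTP-free survival, ROC threshold discovery and green/gray/red bands.

.u_col <- function(cohort, m) {
  col <- paste0("u", m)
  if (!col %in% names(cohort))
    stop("cohort has no unablated-percentage column `", col, "`",
         call. = FALSE)
  cohort[[col]]
}

#' Per-class completeness table at one margin
#'
#' Cross-tabulates the five completeness classes against local tumor
#' progression at margin `m`, with per-class LTP percentages and an
#' association p-value from [association_test()] (computed over the
#' non-empty classes).
#'
#' @param cohort Cohort data frame with `residual_pct`, `u<m>`, `ltp`.
#' @param m Margin, mm.
#' @param residual_tol_pct Residual tolerance passed to
#'   [classify_ablation()].
#' @return List of class `classification_table`: `margin_mm`, data frame
#'   `table` (class, total, ltp, ltp_pct) and `p_value` (NA when fewer than
#'   two classes are occupied or only one outcome is present).
#' @export
classification_table <- function(cohort, m, residual_tol_pct = 0) {
  u <- .u_col(cohort, m)
  cls <- factor(classify_ablation(cohort$residual_pct, u, residual_tol_pct),
                levels = completeness_classes())
  total <- as.integer(table(cls))
  ltp <- as.integer(tapply(cohort$ltp, cls, sum, default = 0L))
  tab <- data.frame(class = completeness_classes(), total = total, ltp = ltp,
                    ltp_pct = ifelse(total > 0, 100 * ltp / total, 0),
                    stringsAsFactors = FALSE)
  occ <- tab$total > 0
  p <- if (sum(occ) >= 2 && length(unique(cohort$ltp)) == 2)
    association_test(cbind(tab$ltp[occ], tab$total[occ] - tab$ltp[occ]))
  else NA_real_
  structure(list(margin_mm = m, table = tab, p_value = p),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Completeness at %g mm (association p = %s)\n", x$margin_mm,
              format(x$p_value, digits = 3)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cumulative completeness table at one margin
#'
#' Nested risk groups by minimum coverage of the m-mm margin: 100%
#' (U = 0), >95% (U < 5), >90% (U <= 10) and all ablations; residual-tumor
#' cases belong only to "all". Each finer group is a subset of the coarser
#' ones, so totals are prefix sums of the per-class table.
#'
#' @inheritParams classification_table
#' @return Data frame with `group`, `total`, `ltp`, `ltp_pct`.
#' @export
cumulative_table <- function(cohort, m, residual_tol_pct = 0) {
  u <- .u_col(cohort, m)
  cls <- factor(classify_ablation(cohort$residual_pct, u, residual_tol_pct),
                levels = completeness_classes())
  idx <- as.integer(cls)  # 1..5 in coverage order
  groups <- list(`100% SM` = 1L, `>95% SM` = 2L, `>90% SM` = 3L, All = 5L)
  rows <- lapply(names(groups), function(g) {
    sel <- idx <= groups[[g]]
    data.frame(group = g, total = sum(sel), ltp = sum(cohort$ltp[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ltp_pct <- ifelse(out$total > 0, 100 * out$ltp / out$total, 0)
  out
}

#' Association test for a contingency table
#'
#' Chi-square test of independence without continuity correction by
#' default; for 2x2 tables with any expected count below 5 the two-sided
#' Fisher exact test (hypergeometric) is used instead.
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @param correct Apply the Yates continuity correction to the chi-square
#'   statistic (default FALSE).
#' @return Two-sided p-value.
#' @export
association_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin total is zero", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < 5))
    return(fisher.test(tab)$p.value)
  suppressWarnings(chisq.test(tab, correct = correct)$p.value)
}

#' Kaplan-Meier LTP-free survival
#'
#' Product-limit estimate of freedom from local tumor progression;
#' censored cases (no LTP at last follow-up) leave the risk set without an
#' event step.
#'
#' @param time_months Positive follow-up or event times.
#' @param event 0/1 event indicator (1 = LTP).
#' @return List of class `survival_curve`: data frame `curve` with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, plus `n` and
#'   `n_events`.
#' @export
km_estimator <- function(time_months, event) {
  if (length(time_months) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(length(event) == length(time_months), all(time_months > 0))
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1)
  structure(list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event,
                                    n_censor = fit$n.censor,
                                    surv = fit$surv),
                 n = length(time_months), n_events = sum(event)),
            class = "survival_curve")
}

#' Survival probability at given times
#' @param km A `survival_curve`.
#' @param times Times (months) at which to evaluate S(t).
#' @return Numeric vector of survival probabilities (1 before the first
#'   event).
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "survival_curve"))
  vapply(times, function(t) {
    i <- which(km$curve$time <= t)
    if (length(i) == 0) 1 else km$curve$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test between groups
#'
#' Standard observed-minus-expected chi-square across pooled event times.
#'
#' @param time_months Positive times.
#' @param event 0/1 event indicator.
#' @param group Group labels (>= 2 groups).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time_months, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need at least two groups", call. = FALSE)
  if (sum(event) == 0) stop("no events in any group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' ROC analysis of unablated percentage against LTP
#'
#' Higher unablated percentages predict LTP. Thresholds are placed at
#' midpoints between consecutive distinct values (plus sentinels beyond
#' the range); at threshold c, sensitivity is the fraction of LTP cases
#' with value > c, specificity the fraction of non-LTP cases with
#' value <= c. AUC is computed by the Mann-Whitney concordant-pair count
#' with ties counting one half, which equals the trapezoidal area under
#' the sweep.
#'
#' @param values Unablated percentages (or any risk score).
#' @param labels 0/1 LTP labels; both classes must be present.
#' @param step Grid step of the reported 100%-sensitivity cut-off.
#' @return List of class `roc_result`: `auc`, data frame `sweep`
#'   (`threshold`, `sensitivity`, `specificity`), `sens100_threshold` and
#'   `spec_at_sens100`.
#' @export
roc_analysis <- function(values, labels, step = 0.1) {
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both LTP and non-LTP cases are required", call. = FALSE)
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  v <- sort(unique(values))
  thr <- c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
  sweep <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(c) mean(pos > c), numeric(1)),
    specificity = vapply(thr, function(c) mean(neg <= c), numeric(1)))
  s100 <- sens100_threshold(values, labels, step = step)
  structure(list(auc = auc, sweep = sweep,
                 sens100_threshold = s100$threshold,
                 spec_at_sens100 = s100$specificity),
            class = "roc_result")
}

#' 100%-sensitivity threshold on a one-decimal grid
#'
#' The largest cut-off on the reporting grid (default 0.1 percentage
#' points) lying strictly below the unablated percentage of every LTP
#' case: any tumor at or below it would be a true negative, so flagging
#' values above it keeps sensitivity for LTP at 100%. Floored at 0.
#'
#' @param values Unablated percentages.
#' @param labels 0/1 LTP labels; at least one LTP case required.
#' @param step Grid step (default 0.1).
#' @return List with `threshold` and `specificity` (fraction of non-LTP
#'   cases at or below the threshold; NA if there are none).
#' @export
sens100_threshold <- function(values, labels, step = 0.1) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0)
    stop("no LTP cases: 100%-sensitivity threshold undefined", call. = FALSE)
  stopifnot(step > 0)
  mn <- min(values[labels == 1])
  k <- floor(mn / step + 1e-9)
  if (k * step >= mn - 1e-9) k <- k - 1
  thr <- max(0, k * step)
  neg <- values[labels == 0]
  spec <- if (length(neg)) mean(neg <= thr + 1e-9) else NA_real_
  list(threshold = thr, specificity = spec)
}

#' Green / gray / red zone bands
#'
#' Partitions the unablated-percentage axis at one margin: values below
#' the 100%-sensitivity cut-off `g` were only ever seen without LTP
#' (green); values above the largest non-LTP value `r` were only seen
#' with LTP (red); `[g, r]` is the gray zone where both outcomes occur.
#' The gray band is empty iff the two outcome groups separate perfectly.
#'
#' @inheritParams roc_analysis
#' @return List of class `zone_bands`: `green_upper` (g), `red_lower` (r),
#'   `gray` (c(g, r) or NULL when empty).
#' @export
zone_bands <- function(values, labels, step = 0.1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both LTP and non-LTP cases are required", call. = FALSE)
  g <- sens100_threshold(values, labels, step = step)$threshold
  r <- max(values[labels == 0])
  structure(list(green_upper = g, red_lower = r,
                 gray = if (g <= r) c(g, r) else NULL),
            class = "zone_bands")
}

#' Pooled two-sample t test
#'
#' Unpaired two-sided Student's t test with pooled variance, used to
#' compare continuous measures (e.g. unablated percentages) between LTP
#' and non-LTP tumors. Degenerate cases are resolved by limits: two
#' identical constant groups give p = 1; constant groups with different
#' means give p = 0.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `statistic` (t), `df`, `p_value`.
#' @export
compare_groups_continuous <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (equal) 0 else Inf * sign(mean(x) - mean(y)),
                df = df, p_value = if (equal) 1 else 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Univariate covariate screen against LTP
#'
#' Dichotomizes continuous covariates (size at 30 mm, age at 60 years) and
#' runs [association_test()] on each 2x2 covariate-by-LTP table, mirroring
#' a univariate risk-factor analysis. No multiplicity adjustment is
#' applied.
#'
#' @param cohort Cohort data frame.
#' @param covariates Character vector of columns to screen; defaults to the
#'   standard set present in the cohort.
#' @return Data frame with one row per covariate: counts
#'   (`yes_ltp`, `yes_total`, `no_ltp`, `no_total`) and `p_value`.
#' @export
covariate_screen <- function(cohort, covariates = NULL) {
  work <- cohort
  if ("size_mm" %in% names(work)) work$size_ge_30mm <- as.integer(work$size_mm >= 30)
  if ("age" %in% names(work)) work$age_gt_60y <- as.integer(work$age > 60)
  default <- intersect(c("size_ge_30mm", "age_gt_60y", "male", "subcapsular",
                         "vessel", "organ", "prior_ctx", "prior_hr",
                         "adjuvant_ctx"), names(work))
  covariates <- covariates %||% default
  rows <- lapply(covariates, function(cv) {
    x <- work[[cv]]
    if (length(unique(x)) < 2)
      stop("covariate `", cv, "` is constant", call. = FALSE)
    tab <- table(factor(x, levels = c(1, 0)),
                 factor(work$ltp, levels = c(1, 0)))
    data.frame(covariate = cv,
               yes_ltp = tab[1, 1], yes_total = sum(tab[1, ]),
               no_ltp = tab[2, 1], no_total = sum(tab[2, ]),
               p_value = association_test(unclass(tab)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
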