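# Confirmatory mass-univariate analysis: per-area quadratic age models
# with Benjamini-Hochberg FDR, and the cohort demographic/motion summary.

#' Center ages on the pooled sample mean
#'
#' `age_cen = age - mean(age)` over the full pooled sample (both groups),
#' and `age_cen_sq = age_cen^2` (centered first, then squared).
#'
#' @param ages numeric vector (>= 3 values, positive variance).
#' @return list with `age_cen` and `age_cen_sq`.
#' @export
center_age <- function(ages) {
  if (length(ages) < 3) stop("need at least 3 ages", call. = FALSE)
  if (stats::var(ages) <= 0) stop("zero age variance", call. = FALSE)
  age_cen <- ages - mean(ages)
  list(age_cen = age_cen, age_cen_sq = age_cen^2)
}

#' Fit one quadratic age model
#'
#' Ordinary least squares `y ~ 1 + age_cen + age_cen_sq`; the p-value is
#' the two-sided t-test on the quadratic coefficient.
#'
#' @param y response vector (one area's S_C or S_D across subjects).
#' @param age_cen,age_cen_sq from [center_age()].
#' @return list with `beta0`, `beta_age`, `beta_age2`, `p_age2`.
#' @export
fit_quadratic <- function(y, age_cen, age_cen_sq) {
  if (length(y) < 4) stop("need at least 4 observations", call. = FALSE)
  fit <- stats::lm(y ~ age_cen + age_cen_sq)
  if (fit$rank < 3)
    stop("rank-deficient design (need > 3 distinct ages)", call. = FALSE)
  cf <- summary(fit)$coefficients
  list(beta0 = cf["(Intercept)", 1],
       beta_age = cf["age_cen", 1],
       beta_age2 = cf["age_cen_sq", 1],
       p_age2 = cf["age_cen_sq", 4])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) ( m p_(j) / j )` clipped
#' to 1, mapped back to input order.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Mass-univariate quadratic age regression over all areas
#'
#' Fits the quadratic age model per area and metric (S_C and S_D) with
#' ages centered on the pooled sample mean, then applies BH correction —
#' by default within each metric's family of N tests, since the two
#' metrics are reported separately (a `"joint"` family over all 2N tests
#' is available).
#'
#' @param stack a `cohort_stack` (one S_C and one S_D row per subject).
#' @param family `"per_metric"` (default) or `"joint"`.
#' @return data.frame with one row per area x metric: `area`, `metric`,
#'   `beta0`, `beta_age`, `beta_age2`, `p_age2`, `q_age2`; attribute
#'   `min_q` gives the minimum adjusted p per metric.
#' @export
run_mass_univariate <- function(stack, family = c("per_metric", "joint")) {
  family <- match.arg(family)
  stopifnot(inherits(stack, "cohort_stack"))
  subj <- stack$subjects
  cen <- center_age(subj$age_years)
  areas <- colnames(stack$brain)
  res <- list()
  for (metric in stack$conditions) {
    # one row per subject in subjects-table order, both groups pooled
    ridx <- vapply(subj$subject_id, function(id)
      which(stack$subject_of_row == id & stack$row_condition == metric)[1],
      integer(1))
    Y <- stack$brain[ridx, , drop = FALSE]
    for (j in seq_along(areas)) {
      f <- fit_quadratic(Y[, j], cen$age_cen, cen$age_cen_sq)
      res[[length(res) + 1]] <- data.frame(
        area = areas[j], metric = metric,
        beta0 = f$beta0, beta_age = f$beta_age, beta_age2 = f$beta_age2,
        p_age2 = f$p_age2, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, res)
  if (family == "per_metric") {
    tab$q_age2 <- NA_real_
    for (metric in unique(tab$metric)) {
      sel <- tab$metric == metric
      tab$q_age2[sel] <- bh_adjust(tab$p_age2[sel])
    }
  } else {
    tab$q_age2 <- bh_adjust(tab$p_age2)
  }
  attr(tab, "min_q") <- tapply(tab$q_age2, tab$metric, min)
  tab
}

#' Cohort demographic and head-motion statistics
#'
#' Per-group age summaries plus a pooled-variance two-sample t-test on
#' mean framewise displacement between the two groups, with Cohen's d
#' (mean difference over pooled SD).  The pooled test has
#' `df = n1 + n2 - 2`.
#'
#' @param subjects subject data.frame with exactly two groups, each
#'   n >= 2.
#' @return list of class `"cohort_stats"`: `age` (per-group data.frame of
#'   n/mean/min/max), `fd_t`, `fd_df`, `fd_p`, `cohens_d`, `max_fd`.
#' @export
cohort_stats <- function(subjects) {
  groups <- unique(subjects$group)
  if (length(groups) != 2)
    stop("cohort_stats requires exactly two groups", call. = FALSE)
  ns <- table(subjects$group)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  age <- do.call(rbind, lapply(groups, function(g) {
    a <- subjects$age_years[subjects$group == g]
    data.frame(group = g, n = length(a), mean = mean(a),
               min = min(a), max = max(a), stringsAsFactors = FALSE)
  }))
  x1 <- subjects$mean_fd_mm[subjects$group == groups[1]]
  x2 <- subjects$mean_fd_mm[subjects$group == groups[2]]
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  tval <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  structure(
    list(age = age,
         fd_t = tval, fd_df = df,
         fd_p = 2 * stats::pt(-abs(tval), df),
         cohens_d = (mean(x1) - mean(x2)) / sqrt(sp2),
         max_fd = max(subjects$mean_fd_mm)),
    class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  print(x$age, row.names = FALSE)
  cat(sprintf("mean FD: t(%d) = %.2f, p = %.3f, Cohen's d = %.3f, max FD = %.3f mm\n",
              x$fd_df, x$fd_t, x$fd_p, x$cohens_d, x$max_fd))
  invisible(x)
}
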