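# Behavior PLS of areal (de)coupling against age: stacked brain matrix,
# per-cell brain-age correlations, SVD into latent variables, permutation
# significance, bootstrap-ratio stability, network summaries, and a head
# motion check.

#' Stack coupling profiles into the PLS brain matrix
#'
#' Each subject contributes two rows, one per condition (S_C, S_D), over
#' the N areas.  Rows are ordered group-major, condition-minor: all of
#' group 1's S_C rows, then its S_D rows, then group 2's S_C rows, and so
#' on.  For a 19 + 14 cohort over 360 areas this is the 66 x 360 brain
#' matrix, with an aligned 66-element age vector (each subject's age
#' appearing once per condition row).
#'
#' @param profiles named list of `coupling_profile`s (by subject id), all
#'   over identical node sets.
#' @param subjects subject data.frame (see [read_subjects()]).
#' @param group_order order of groups in the stack; default puts
#'   `"control"` first when present, otherwise order of appearance.
#' @return object of class `"cohort_stack"`: list with `brain` (matrix),
#'   `age`, `row_group`, `row_condition`, `subject_of_row`, `groups`,
#'   `conditions`, and the `subjects` table.
#' @export
stack_cohort <- function(profiles, subjects, group_order = NULL) {
  ids <- subjects$subject_id
  if (anyDuplicated(ids)) stop("duplicate subject", call. = FALSE)
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop("missing coupling profile for: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  nodes <- names(profiles[[ids[1]]]$s_c)
  for (id in ids) {
    p <- profiles[[id]]
    if (is.null(p$s_c) || is.null(p$s_d))
      stop("subject ", id, " missing S_C or S_D", call. = FALSE)
    if (!identical(names(p$s_c), nodes) || !identical(names(p$s_d), nodes))
      stop("node set mismatch across subjects (", id, ")", call. = FALSE)
  }
  if (is.null(group_order)) {
    seen <- unique(subjects$group)
    group_order <- c(intersect("control", seen), setdiff(seen, "control"))
  }
  conditions <- c("S_C", "S_D")
  rows <- list(); age <- c(); row_group <- c(); row_condition <- c()
  subject_of_row <- c()
  for (g in group_order) {
    gsub <- subjects[subjects$group == g, ]
    for (cond in conditions) {
      for (i in seq_len(nrow(gsub))) {
        id <- gsub$subject_id[i]
        v <- if (cond == "S_C") profiles[[id]]$s_c else profiles[[id]]$s_d
        rows[[length(rows) + 1]] <- v
        age <- c(age, gsub$age_years[i])
        row_group <- c(row_group, g)
        row_condition <- c(row_condition, cond)
        subject_of_row <- c(subject_of_row, id)
      }
    }
  }
  brain <- do.call(rbind, rows)
  rownames(brain) <- paste(subject_of_row, row_condition, sep = ".")
  colnames(brain) <- nodes
  structure(list(brain = brain, age = age, row_group = row_group,
                 row_condition = row_condition,
                 subject_of_row = subject_of_row,
                 groups = group_order, conditions = conditions,
                 subjects = subjects),
            class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  cat("cohort_stack: ", nrow(x$brain), " rows x ", ncol(x$brain),
      " areas (", length(x$groups), " groups x ", length(x$conditions),
      " conditions)\n", sep = "")
  invisible(x)
}

# Pearson correlation of a vector with every column of X; columns with
# zero variance get correlation 0 (count returned as attribute).
corr_with_columns <- function(a, X) {
  ac <- a - mean(a)
  Xc <- sweep(X, 2, colMeans(X))
  sa <- sqrt(sum(ac^2))
  sx <- sqrt(colSums(Xc^2))
  degen <- sx <= 0
  sx[degen] <- 1
  r <- as.numeric(crossprod(ac, Xc)) / (sa * sx)
  r[degen] <- 0
  attr(r, "n_degenerate") <- sum(degen)
  r
}

# rows of the stack belonging to one group x condition cell
cell_rows <- function(stack, g, cond)
  which(stack$row_group == g & stack$row_condition == cond)

cell_labels <- function(stack)
  unlist(lapply(stack$groups, function(g)
    paste(g, stack$conditions, sep = ".")), use.names = FALSE)

#' Brain-age correlation matrix
#'
#' For each group x condition cell, the Pearson correlation between age
#' and each area's (de)coupling value across that cell's subjects.  Cells
#' are stacked group-major, condition-minor into a K x N matrix (K = number
#' of groups x conditions; 4 for the two-group design).  Areas with zero
#' variance within a cell get correlation 0 with a warning.
#'
#' @param stack a `cohort_stack`.
#' @param ages optional replacement age vector aligned to the stack rows
#'   (used internally by the permutation test).
#' @param warn warn about degenerate areas (default `TRUE`).
#' @return K x N matrix with cell row names.
#' @export
brain_age_correlations <- function(stack, ages = NULL, warn = TRUE) {
  stopifnot(inherits(stack, "cohort_stack"))
  if (is.null(ages)) ages <- stack$age
  out <- list()
  n_degen <- 0
  for (g in stack$groups) {
    for (cond in stack$conditions) {
      idx <- cell_rows(stack, g, cond)
      if (length(idx) < 3)
        stop("cell ", g, " x ", cond, " has fewer than 3 subjects",
             call. = FALSE)
      a <- ages[idx]
      if (stats::var(a) <= 0)
        stop("zero age variance in cell ", g, " x ", cond, call. = FALSE)
      r <- corr_with_columns(a, stack$brain[idx, , drop = FALSE])
      n_degen <- n_degen + attr(r, "n_degenerate")
      out[[paste(g, cond, sep = ".")]] <- as.numeric(r)
    }
  }
  if (n_degen > 0 && warn)
    warning(n_degen, " zero-variance area/cell correlation(s) set to 0",
            call. = FALSE)
  R <- do.call(rbind, out)
  colnames(R) <- colnames(stack$brain)
  R
}

#' Singular value decomposition of the correlation matrix
#'
#' Decomposes the K x N brain-age correlation matrix into K orthogonal
#' latent variables: `R = U diag(d) V'` with design saliences `U` (K x K),
#' singular values `d`, and brain saliences `V` (N x K).  Sign convention:
#' within each latent variable the design-salience entry of largest
#' magnitude is positive.
#'
#' @param R correlation matrix from [brain_age_correlations()].
#' @return list with `singular_values`, `brain_saliences` (N x K),
#'   `design_saliences` (K x K).
#' @export
pls_decompose <- function(R) {
  if (anyNA(R) || any(!is.finite(R)))
    stop("non-finite entries in correlation matrix", call. = FALSE)
  K <- nrow(R)
  if (ncol(R) < K) stop("need at least K areas", call. = FALSE)
  s <- svd(R, nu = K, nv = K)
  U <- s$u; V <- s$v; d <- s$d[seq_len(K)]
  for (k in seq_len(K)) {
    if (U[which.max(abs(U[, k])), k] < 0) {
      U[, k] <- -U[, k]; V[, k] <- -V[, k]
    }
  }
  rownames(U) <- rownames(R)
  rownames(V) <- colnames(R)
  colnames(U) <- colnames(V) <- paste0("LV", seq_len(K))
  list(singular_values = d, brain_saliences = V, design_saliences = U)
}

#' Individual brain scores and their age correlations
#'
#' A subject-condition row's brain score on latent variable k is its
#' projection onto that LV's brain salience: `scores = brain %*% V`.  The
#' Pearson correlation of score with age within each group x condition
#' cell expresses the LV at the individual level.
#'
#' @param stack a `cohort_stack`.
#' @param brain_saliences N x K matrix from [pls_decompose()].
#' @return list with `scores` (rows x K) and `score_age_correlations`
#'   (cells x K); degenerate (constant) scores give correlation 0 with a
#'   warning.
#' @export
brain_scores <- function(stack, brain_saliences) {
  scores <- stack$brain %*% brain_saliences
  K <- ncol(scores)
  labs <- cell_labels(stack)
  sac <- matrix(NA_real_, length(labs), K,
                dimnames = list(labs, colnames(scores)))
  degen <- 0
  for (g in stack$groups) for (cond in stack$conditions) {
    idx <- cell_rows(stack, g, cond)
    for (k in seq_len(K)) {
      sc <- scores[idx, k]
      if (stats::var(sc) <= 0) {
        sac[paste(g, cond, sep = "."), k] <- 0
        degen <- degen + 1
      } else {
        sac[paste(g, cond, sep = "."), k] <- stats::cor(sc, stack$age[idx])
      }
    }
  }
  if (degen > 0)
    warning(degen, " degenerate score-age correlation(s) reported as 0",
            call. = FALSE)
  list(scores = scores, score_age_correlations = sac)
}

# singular values under one age assignment (helper shared by permutation
# and exhaustive enumeration); stack brain is fixed, only ages move.
singular_values_for_ages <- function(stack, ages) {
  R <- brain_age_correlations(stack, ages = ages, warn = FALSE)
  svd(R, nu = 0, nv = 0)$d[seq_len(nrow(R))]
}

#' Permutation p-values for the latent variables
#'
#' Subject ages are shuffled across the whole sample (each subject's S_C
#' and S_D rows keep their common, shuffled age; group membership and
#' brain rows are untouched), correlations and SVD are recomputed, and the
#' p-value of LV k is the fraction of permutations whose k-th singular
#' value strictly exceeds the observed one — no +1 smoothing, so the
#' smallest reportable p is 0 (flagged as `< 1/n_perm` in written output).
#'
#' @param stack a `cohort_stack`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all `n!` age permutations instead of
#'   sampling (only sensible for tiny cohorts; capped at 8 subjects).
#' @return list with `perm_p`, `observed` singular values, `n_perm`.
#' @export
permutation_pvalues <- function(stack, n_perm = 10000, seed = NULL,
                                exhaustive = FALSE) {
  stopifnot(inherits(stack, "cohort_stack"))
  if (!exhaustive && n_perm < 1) stop("n_perm >= 1 required", call. = FALSE)
  subj <- stack$subjects
  subj_age <- stats::setNames(subj$age_years, subj$subject_id)
  row_of_subject <- match(stack$subject_of_row, subj$subject_id)
  observed <- singular_values_for_ages(stack, stack$age)
  K <- length(observed)

  perm_sets <- NULL
  if (exhaustive) {
    n <- nrow(subj)
    if (n > 8) stop("exhaustive enumeration capped at 8 subjects",
                    call. = FALSE)
    perm_sets <- all_permutations(n)
    n_perm <- nrow(perm_sets)
  } else if (!is.null(seed)) set.seed(seed)

  exceed <- numeric(K)
  for (b in seq_len(n_perm)) {
    ord <- if (exhaustive) perm_sets[b, ] else sample(nrow(subj))
    perm_age_subj <- subj_age[ord]            # shuffled over subjects
    ages <- as.numeric(perm_age_subj[row_of_subject])
    d <- singular_values_for_ages(stack, ages)
    exceed <- exceed + (d > observed)
  }
  list(perm_p = exceed / n_perm, observed = observed, n_perm = n_perm)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Orthogonal Procrustes rotation T minimizing ||B T - A||_F
procrustes_rotation <- function(B, A) {
  s <- svd(crossprod(B, A))
  s$u %*% t(s$v)
}

#' Bootstrap ratios and confidence intervals for the brain saliences
#'
#' Subjects are resampled with replacement within group (each subject's
#' S_C and S_D rows travel together); correlations and SVD are recomputed
#' per draw and the bootstrap saliences are aligned to the observed ones
#' by an orthogonal Procrustes rotation (resolving axis reflection and
#' rotation).  The bootstrap ratio of area i on LV k is the observed
#' salience over the standard deviation of the aligned bootstrap
#' saliences; 95% CIs are the 2.5/97.5 percentiles of the aligned
#' bootstrap areal correlation patterns (`R_boot' U_aligned`).  Draws
#' leaving any cell with fewer than 3 distinct subjects are redrawn (at
#' most 100 attempts each).
#'
#' @param stack a `cohort_stack`.
#' @param decomposition observed [pls_decompose()] output.
#' @param n_boot bootstrap iterations (default 1000, >= 2).
#' @param seed integer seed for the bootstrap stream.
#' @return list with `bsr` (N x K; `Inf` sentinel where the bootstrap SE
#'   is 0, with a warning), `ci_low`, `ci_high` (N x K), `n_boot`.
#' @export
bootstrap_ratios <- function(stack, decomposition, n_boot = 1000,
                             seed = NULL) {
  stopifnot(inherits(stack, "cohort_stack"))
  if (n_boot < 2) stop("n_boot >= 2 required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  V_obs <- decomposition$brain_saliences
  N <- nrow(V_obs); K <- ncol(V_obs)
  subj <- stack$subjects

  sal_arr <- array(NA_real_, c(N, K, n_boot))
  cor_arr <- array(NA_real_, c(N, K, n_boot))
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(100)) {
      draw <- unlist(lapply(stack$groups, function(g) {
        pool <- subj$subject_id[subj$group == g]
        sample(pool, length(pool), replace = TRUE)
      }), use.names = FALSE)
      if (all(vapply(stack$groups, function(g)
        length(unique(draw[subj$group[match(draw, subj$subject_id)] == g])),
        integer(1)) >= 3)) break
      if (attempt == 100)
        stop("bootstrap could not draw >= 3 distinct subjects per cell",
             call. = FALSE)
    }
    bsub <- subj[match(draw, subj$subject_id), ]
    bsub$subject_id <- sprintf("bs%03d", seq_along(draw))  # keep rows unique
    prof_ids <- draw
    bstack <- stack_boot(stack, bsub, prof_ids)
    R_b <- brain_age_correlations(bstack, warn = FALSE)
    dec_b <- pls_decompose(R_b)
    Tr <- procrustes_rotation(dec_b$brain_saliences, V_obs)
    sal_arr[, , b] <- dec_b$brain_saliences %*% Tr
    cor_arr[, , b] <- t(R_b) %*% (dec_b$design_saliences %*% Tr)
  }
  se <- apply(sal_arr, c(1, 2), stats::sd)
  zero_se <- se == 0
  if (any(zero_se))
    warning(sum(zero_se), " areal feature(s) with zero bootstrap SE; ",
            "BSR reported as Inf", call. = FALSE)
  bsr <- V_obs / se
  bsr[zero_se] <- Inf * sign(V_obs[zero_se])
  ci_low <- apply(cor_arr, c(1, 2), stats::quantile, probs = 0.025)
  ci_high <- apply(cor_arr, c(1, 2), stats::quantile, probs = 0.975)
  dimnames(bsr) <- dimnames(ci_low) <- dimnames(ci_high) <- dimnames(V_obs)
  list(bsr = bsr, ci_low = ci_low, ci_high = ci_high, n_boot = n_boot)
}

# rebuild a stack for a bootstrap draw by pulling the original subjects'
# rows (profiles are already inside stack$brain)
stack_boot <- function(stack, bsub, original_ids) {
  rows <- list(); age <- c(); row_group <- c(); row_condition <- c()
  subject_of_row <- c()
  for (g in stack$groups) {
    sel <- which(bsub$group == g)
    for (cond in stack$conditions) {
      for (i in sel) {
        orig <- original_ids[i]
        src <- which(stack$subject_of_row == orig &
                       stack$row_condition == cond)[1]
        rows[[length(rows) + 1]] <- stack$brain[src, ]
        age <- c(age, bsub$age_years[i])
        row_group <- c(row_group, g)
        row_condition <- c(row_condition, cond)
        subject_of_row <- c(subject_of_row, bsub$subject_id[i])
      }
    }
  }
  brain <- do.call(rbind, rows)
  colnames(brain) <- colnames(stack$brain)
  structure(list(brain = brain, age = age, row_group = row_group,
                 row_condition = row_condition,
                 subject_of_row = subject_of_row,
                 groups = stack$groups, conditions = stack$conditions,
                 subjects = bsub),
            class = "cohort_stack")
}

#' Network summary of supra-threshold bootstrap ratios
#'
#' Areas whose |BSR| exceeds the threshold (2.58, the two-sided 99% normal
#' critical value) are the reliable contributors to a latent variable;
#' their BSRs are averaged within network, separately for positive
#' (pattern) and negative (opposite pattern) directions.
#'
#' @param bsr numeric vector of bootstrap ratios for one LV (named by
#'   area) or an N x K matrix (summarized per column).
#' @param network_of named character vector area -> network.
#' @param threshold BSR threshold (default 2.58).
#' @return data.frame with columns `lv`, `network`, `n_positive`,
#'   `mean_positive_bsr`, `n_negative`, `mean_negative_bsr` (means are
#'   `NA` where no area passes).
#' @export
network_summary <- function(bsr, network_of, threshold = 2.58) {
  if (is.matrix(bsr)) {
    out <- do.call(rbind, lapply(seq_len(ncol(bsr)), function(k) {
      s <- network_summary(bsr[, k], network_of, threshold)
      s$lv <- k
      s
    }))
    return(out[, c("lv", setdiff(names(out), "lv"))])
  }
  areas <- names(bsr)
  if (is.null(areas) || !all(areas %in% names(network_of)))
    stop("network labels must cover all areas", call. = FALSE)
  nets <- unique(network_of[areas])
  res <- lapply(nets, function(nw) {
    v <- bsr[network_of[areas] == nw]
    pos <- v[v > threshold]
    neg <- v[v < -threshold]
    data.frame(network = nw,
               n_positive = length(pos),
               mean_positive_bsr = if (length(pos)) mean(pos) else NA_real_,
               n_negative = length(neg),
               mean_negative_bsr = if (length(neg)) mean(neg) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$lv <- 1L
  out[, c("lv", "network", "n_positive", "mean_positive_bsr",
          "n_negative", "mean_negative_bsr")]
}

#' Head-motion check on brain scores
#'
#' Pearson correlation (with two-sided p) between each latent variable's
#' brain scores and subjects' mean framewise displacement, separately per
#' condition.  Small, non-significant correlations argue that motion does
#' not drive the latent patterns; the criterion is reported, not enforced.
#'
#' @param scores row x K score matrix from [brain_scores()].
#' @param stack the `cohort_stack` the scores came from.
#' @return data.frame with `lv`, `condition`, `r`, `p`; degenerate FD or
#'   scores give `r = 0`, `p = 1` with a warning.
#' @export
motion_check <- function(scores, stack) {
  fd <- stats::setNames(stack$subjects$mean_fd_mm,
                        stack$subjects$subject_id)
  if (anyNA(fd)) stop("missing FD", call. = FALSE)
  K <- ncol(scores)
  out <- list()
  for (cond in stack$conditions) {
    idx <- which(stack$row_condition == cond)
    f <- as.numeric(fd[stack$subject_of_row[idx]])
    for (k in seq_len(K)) {
      sc <- scores[idx, k]
      if (stats::var(f) <= 0 || stats::var(sc) <= 0) {
        warning("degenerate variance in motion check; r reported as 0",
                call. = FALSE)
        r <- 0; p <- 1
      } else {
        ct <- stats::cor.test(sc, f)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1]] <- data.frame(lv = k, condition = cond,
                                           r = r, p = p)
    }
  }
  do.call(rbind, out)
}

#' Behavior PLS of areal (de)coupling against age
#'
#' End-to-end wrapper: stacks profiles, computes per-cell brain-age
#' correlations, decomposes them into latent variables, and runs the
#' permutation test, bootstrap, network summary and motion check.
#'
#' @param profiles named list of `coupling_profile`s.
#' @param subjects subject data.frame.
#' @param network_of named character vector area -> network.
#' @param n_perm,n_boot permutation and bootstrap iterations (study
#'   defaults 10000 and 1000).
#' @param bsr_threshold network-summary BSR threshold (default 2.58).
#' @param seed master seed; permutation and bootstrap use seeds derived
#'   from it.
#' @param group_order passed to [stack_cohort()].
#' @return object of class `"pls_result"` collecting all components.
#' @export
pls_brain_age <- function(profiles, subjects, network_of,
                          n_perm = 10000, n_boot = 1000,
                          bsr_threshold = 2.58, seed = 1,
                          group_order = NULL) {
  stack <- stack_cohort(profiles, subjects, group_order = group_order)
  R <- brain_age_correlations(stack)
  dec <- pls_decompose(R)
  perm <- permutation_pvalues(stack, n_perm = n_perm,
                              seed = seed + 1L)
  boot <- bootstrap_ratios(stack, dec, n_boot = n_boot, seed = seed + 2L)
  sc <- brain_scores(stack, dec$brain_saliences)
  structure(
    list(stack = stack,
         correlations = R,
         singular_values = dec$singular_values,
         brain_saliences = dec$brain_saliences,
         design_saliences = dec$design_saliences,
         brain_scores = sc$scores,
         score_age_correlations = sc$score_age_correlations,
         perm_p = perm$perm_p, n_perm = perm$n_perm,
         bsr = boot$bsr, ci_low = boot$ci_low, ci_high = boot$ci_high,
         n_boot = boot$n_boot,
         bsr_threshold = bsr_threshold,
         network_summary = network_summary(boot$bsr, network_of,
                                           bsr_threshold),
         network_of = network_of,
         motion = motion_check(sc$scores, stack),
         seed = seed),
    class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  K <- length(x$singular_values)
  cat("Behavior PLS: ", nrow(x$stack$brain), " rows x ",
      ncol(x$stack$brain), " areas, ", K, " latent variables\n", sep = "")
  p_lab <- ifelse(x$perm_p == 0, paste0("<", format(1 / x$n_perm)),
                  format(x$perm_p, digits = 3))
  for (k in seq_len(K))
    cat(sprintf("  LV%d: singular value %.4f, perm p %s\n",
                k, x$singular_values[k], p_lab[k]))
  invisible(x)
}
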