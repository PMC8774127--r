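test_that("stacking follows the group-major, condition-minor contract", {
  subs <- make_subjects(c(control = 2, athlete = 2), seed = 51)
  prof <- fake_profiles(subs, n_nodes = 5, seed = 52)
  st <- stack_cohort(prof, subs)
  expect_equal(dim(st$brain), c(8, 5))
  expect_equal(st$row_group,
               c("control", "control", "control", "control",
                 "athlete", "athlete", "athlete", "athlete"))
  expect_equal(st$row_condition,
               rep(c("S_C", "S_C", "S_D", "S_D"), 2))
  # each subject's age appears once per condition row
  for (id in subs$subject_id) {
    idx <- which(st$subject_of_row == id)
    expect_length(idx, 2)
    expect_equal(st$age[idx], rep(subs$age_years[subs$subject_id == id], 2))
  }
  # rows hold the right profile vectors
  expect_equal(unname(st$brain["control01.S_C", ]),
               unname(prof[["control01"]]$s_c))
  expect_equal(unname(st$brain["athlete02.S_D", ]),
               unname(prof[["athlete02"]]$s_d))
})

test_that("stacking errors on missing conditions and duplicates", {
  subs <- make_subjects(c(control = 3, athlete = 3), seed = 53)
  prof <- fake_profiles(subs, n_nodes = 4)
  broken <- prof
  broken[["athlete01"]]$s_d <- NULL
  expect_error(stack_cohort(broken, subs), "missing S_C or S_D")
  dup <- rbind(subs, subs[1, ])
  expect_error(stack_cohort(prof, dup), "duplicate subject")
  short <- prof
  short[["control01"]] <- NULL
  expect_error(stack_cohort(short, subs), "missing coupling profile")
})

test_that("the study design yields a 66 x 360 brain matrix and 4 LVs", {
  subs <- make_subjects(c(athlete = 19, control = 14), seed = 55)
  prof <- fake_profiles(subs, n_nodes = 360, seed = 56)
  st <- stack_cohort(prof, subs)
  expect_equal(dim(st$brain), c(66, 360))
  expect_length(st$age, 66)
  R <- brain_age_correlations(st)
  expect_equal(dim(R), c(4, 360))
  dec <- pls_decompose(R)
  expect_length(dec$singular_values, 4)
})

test_that("brain-age correlations match the textbook Pearson formula", {
  subs <- data.frame(subject_id = c("s1", "s2", "s3"),
                     age_years = c(20, 30, 40), group = "g",
                     mean_fd_mm = 0.1)
  prof <- fake_profiles(subs, n_nodes = 3, seed = 57)
  # make area 1 of S_C perfectly linear in age, area 2 constant
  for (i in 1:3) {
    prof[[i]]$s_c[1] <- c(1, 2, 3)[i]
    prof[[i]]$s_c[2] <- 5
  }
  st <- stack_cohort(prof, subs)
  expect_warning(R <- brain_age_correlations(st), "zero-variance")
  expect_equal(R["g.S_C", 1], 1)
  expect_equal(R["g.S_C", 2], 0)

  # random 6-subject cell against a direct-formula oracle
  subs6 <- make_subjects(c(g = 6), seed = 58)
  prof6 <- fake_profiles(subs6, n_nodes = 7, seed = 59)
  st6 <- stack_cohort(prof6, subs6)
  R6 <- brain_age_correlations(st6)
  a <- subs6$age_years
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  for (j in 1:7) {
    sc <- sapply(subs6$subject_id, function(id) prof6[[id]]$s_c[j])
    expect_equal(R6["g.S_C", j], pearson(a, sc), tolerance = 1e-12)
  }

  # degenerate age variance is a hard error
  subs_const <- subs
  subs_const$age_years <- 30
  expect_error(brain_age_correlations(stack_cohort(prof, subs_const)),
               "age variance")
})

test_that("the SVD decomposition reconstructs and respects conventions", {
  expect_equal(pls_decompose(matrix(c(1, 0, 0, 0), 2, 2))$singular_values,
               c(1, 0))
  set.seed(61)
  R <- matrix(rnorm(4 * 12), 4, 12,
              dimnames = list(paste0("c", 1:4), paste0("a", 1:12)))
  dec <- pls_decompose(R)
  rec <- dec$design_saliences %*% diag(dec$singular_values) %*%
    t(dec$brain_saliences)
  expect_lt(max(abs(rec - R)), 1e-10)
  expect_lt(max(abs(crossprod(dec$brain_saliences) - diag(4))), 1e-9)
  expect_true(all(diff(dec$singular_values) <= 1e-12))
  # sign convention: largest-magnitude design entry positive per LV
  for (k in 1:4) {
    u <- dec$design_saliences[, k]
    expect_gt(u[which.max(abs(u))], 0)
  }
  expect_error(pls_decompose(matrix(c(NA, 1), 1, 2)), "non-finite")
})

test_that("brain scores project the stack and report cell-wise age links", {
  subs <- make_subjects(c(g = 4), seed = 63)
  prof <- fake_profiles(subs, n_nodes = 1, seed = 64)
  st <- stack_cohort(prof, subs)
  sc <- brain_scores(st, matrix(1, 1, 1))
  expect_equal(unname(sc$scores[, 1]), unname(st$brain[, 1]))
  expect_warning(z <- brain_scores(st, matrix(0, 1, 1)), "degenerate")
  expect_equal(unname(z$score_age_correlations[, 1]), c(0, 0))
})

test_that("permutation p-values match exhaustive enumeration on a micro-cohort", {
  subs <- data.frame(subject_id = c("s1", "s2", "s3"),
                     age_years = c(21, 33, 45), group = "g",
                     mean_fd_mm = 0.1)
  prof <- fake_profiles(subs, n_nodes = 4, seed = 65)
  st <- stack_cohort(prof, subs)
  res <- permutation_pvalues(st, exhaustive = TRUE)
  expect_equal(res$n_perm, 6)

  # independent brute-force oracle: enumerate the 6 age assignments and
  # apply the strictly-greater counting rule by hand
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  ages <- subs$age_years
  sv_for <- function(a_subj) {
    a_rows <- a_subj[match(st$subject_of_row, subs$subject_id)]
    R <- rbind(
      sapply(1:4, function(j) cor(a_rows[1:3], st$brain[1:3, j])),
      sapply(1:4, function(j) cor(a_rows[4:6], st$brain[4:6, j])))
    svd(R)$d
  }
  obs <- sv_for(ages)
  counts <- c(0, 0)
  for (p in perms) {
    d <- sv_for(ages[p])
    counts <- counts + (d > obs)
  }
  expect_equal(res$perm_p, counts / 6)
  expect_equal(res$observed, obs, tolerance = 1e-12)
})

test_that("permutations are seeded and validate n_perm", {
  cfg <- small_cohort_config(seed = 67)
  ch <- generate_cohort(cfg)
  prof <- cohort_coupling(ch$connectomes, ch$bolds)
  st <- stack_cohort(prof, ch$subjects)
  p1 <- permutation_pvalues(st, n_perm = 50, seed = 9)
  p2 <- permutation_pvalues(st, n_perm = 50, seed = 9)
  expect_identical(p1$perm_p, p2$perm_p)
  expect_error(permutation_pvalues(st, n_perm = 0), "n_perm")
})

test_that("Procrustes alignment undoes an injected reflection", {
  set.seed(71)
  V <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  reflected <- V %*% diag(c(-1, 1))
  Tr <- neurocouple:::procrustes_rotation(reflected, V)
  expect_lt(max(abs(reflected %*% Tr - V)), 1e-10)
})

test_that("bootstrap returns finite output and flags degenerate SEs", {
  subs <- make_subjects(c(control = 5, athlete = 5), seed = 73)
  prof <- fake_profiles(subs, n_nodes = 6, seed = 74)
  st <- stack_cohort(prof, subs)
  dec <- pls_decompose(brain_age_correlations(st))
  bt <- bootstrap_ratios(st, dec, n_boot = 2, seed = 75)
  expect_true(all(is.finite(bt$bsr) | is.infinite(bt$bsr)))
  expect_equal(dim(bt$bsr), dim(dec$brain_saliences))
  expect_true(all(bt$ci_low <= bt$ci_high))
  expect_error(bootstrap_ratios(st, dec, n_boot = 1), "n_boot")
})

test_that("network summary averages supra-threshold BSRs by direction", {
  bsr <- c(a1 = 3, a2 = -3, a3 = 1)
  nets <- c(a1 = "a", a2 = "a", a3 = "b")
  s <- network_summary(bsr, nets, threshold = 2.58)
  sa <- s[s$network == "a", ]
  expect_equal(sa$n_positive, 1)
  expect_equal(sa$mean_positive_bsr, 3)
  expect_equal(sa$n_negative, 1)
  expect_equal(sa$mean_negative_bsr, -3)
  sb <- s[s$network == "b", ]
  expect_equal(sb$n_positive + sb$n_negative, 0)
  expect_true(is.na(sb$mean_positive_bsr))

  none <- network_summary(c(a1 = 1, a2 = -2), nets[1:2], threshold = 2.58)
  expect_true(all(none$n_positive == 0 & none$n_negative == 0))

  # brute-force filter-and-group oracle over 360 areas / 12 networks
  set.seed(77)
  big <- setNames(rnorm(360, sd = 2), sprintf("a%03d", 1:360))
  bignet <- setNames(rep(sprintf("net%02d", 1:12), each = 30), names(big))
  s2 <- network_summary(big, bignet)
  for (nw in unique(bignet)) {
    v <- big[bignet == nw]
    row <- s2[s2$network == nw, ]
    expect_equal(row$n_positive, sum(v > 2.58))
    expect_equal(row$n_negative, sum(v < -2.58))
    if (row$n_positive > 0)
      expect_equal(row$mean_positive_bsr, mean(v[v > 2.58]))
  }
  expect_equal(sum(s2$n_positive), sum(big > 2.58))
})

test_that("motion check reports degenerate and perfect correlations", {
  subs <- make_subjects(c(g = 5), seed = 79)
  prof <- fake_profiles(subs, n_nodes = 2, seed = 80)
  st <- stack_cohort(prof, subs)
  # scores equal to FD give r = 1
  fd_scores <- matrix(st$subjects$mean_fd_mm[
    match(st$subject_of_row, st$subjects$subject_id)], ncol = 1)
  m <- motion_check(fd_scores, st)
  expect_equal(m$r, rep(1, 2), tolerance = 1e-12)

  st_const <- st
  st_const$subjects$mean_fd_mm <- 0.1
  w <- capture_warnings(mc <- motion_check(fd_scores * 0 + 1, st_const))
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(mc$r, rep(0, 2))
})

test_that("the full PLS wrapper is reproducible for a fixed seed", {
  cfg <- small_cohort_config(seed = 83)
  ch <- generate_cohort(cfg)
  prof <- cohort_coupling(ch$connectomes, ch$bolds)
  r1 <- suppressWarnings(pls_brain_age(prof, ch$subjects, ch$network_of,
                                       n_perm = 30, n_boot = 10, seed = 5))
  r2 <- suppressWarnings(pls_brain_age(prof, ch$subjects, ch$network_of,
                                       n_perm = 30, n_boot = 10, seed = 5))
  expect_identical(r1$perm_p, r2$perm_p)
  expect_identical(r1$bsr, r2$bsr)
  expect_length(r1$singular_values, 4)
  expect_true(all(r1$perm_p >= 0 & r1$perm_p <= 1))
})
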