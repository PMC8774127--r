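test_that("normalized Laplacian matches closed forms and the entrywise oracle", {
  # two nodes: weight cancels under degree normalization
  for (w in c(0.5, 3.5, 100)) {
    A <- matrix(c(0, w, w, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    L <- normalized_laplacian(connectome(A, c(a = "x", b = "y")))
    expect_equal(unname(L), matrix(c(1, -1, -1, 1), 2, 2))
  }

  # unit-weight 4-cycle: spectrum {0, 1, 1, 2}
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1
  A <- A + t(A)
  cyc <- connectome(A, setNames(rep("x", 4), letters[1:4]))
  ev <- decompose_laplacian(normalized_laplacian(cyc))$eigenvalues
  expect_equal(ev, c(0, 1, 1, 2), tolerance = 1e-12)

  # random 8-node graph vs brute-force entrywise definition
  cn <- random_connectome(8, seed = 11)
  L <- normalized_laplacian(cn)
  deg <- rowSums(cn$weights)
  oracle <- diag(8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- oracle[i, j] - cn$weights[i, j] / sqrt(deg[i] * deg[j])
  expect_lt(max(abs(L - oracle)), 1e-12)
})

test_that("isolated nodes are a hard error naming the node", {
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "iso"), c("a", "b", "iso")))
  A[1, 2] <- A[2, 1] <- 1
  cn <- connectome(A, c(a = "x", b = "x", iso = "x"))
  expect_error(normalized_laplacian(cn), "iso")
})

test_that("eigendecomposition satisfies its spectral contracts", {
  # 2-node closed form
  L2 <- matrix(c(1, -1, -1, 1), 2, 2)
  sp <- decompose_laplacian(L2)
  expect_equal(sp$eigenvalues, c(0, 2), tolerance = 1e-12)
  expect_equal(abs(sp$eigenvectors[, 1]), rep(1 / sqrt(2), 2))
  expect_equal(abs(sp$eigenvectors[, 2]), rep(1 / sqrt(2), 2))
  # sign convention: leading large component positive
  expect_true(all(apply(sp$eigenvectors, 2, function(v)
    v[which(abs(v) > 1e-10)[1]] > 0)))

  cn <- random_connectome(8, seed = 13)
  L <- normalized_laplacian(cn)
  sp <- decompose_laplacian(L)
  # reconstruction and orthonormality
  expect_lt(max(abs(L - sp$eigenvectors %*% diag(sp$eigenvalues) %*%
                      t(sp$eigenvectors))), 1e-8)
  expect_lt(max(abs(crossprod(sp$eigenvectors) - diag(8))), 1e-9)
  # connected graph: eigenvalue 0 with multiplicity 1, spectrum in [0, 2]
  expect_equal(sum(abs(sp$eigenvalues) < 1e-9), 1)
  expect_true(all(sp$eigenvalues > -1e-9 & sp$eigenvalues < 2 + 1e-9))

  # permutation invariance of the spectrum
  perm <- sample(8)
  Lp <- L[perm, perm]
  expect_equal(decompose_laplacian(Lp)$eigenvalues, sp$eigenvalues,
               tolerance = 1e-9)

  expect_error(decompose_laplacian(matrix(c(1, 2, 0, 1), 2, 2)),
               "asymmetric")
})

test_that("graph Fourier transform concentrates constant signals and is unitary", {
  A <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sp <- decompose_laplacian(normalized_laplacian(connectome(A, c(a = "x", b = "x"))))
  X <- matrix(c(1, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  sb <- graph_fourier_transform(sp, parcellated_bold(X))
  expect_equal(abs(sb$coefficients[1, 1]), sqrt(2), tolerance = 1e-12)
  expect_equal(sb$coefficients[2, 1], 0, tolerance = 1e-12)

  zero <- graph_fourier_transform(sp, parcellated_bold(
    matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))))
  expect_equal(unname(zero$esd), c(0, 0))
})

test_that("median energy split follows the smallest-prefix rule", {
  expect_equal(median_energy_split(c(4, 0, 0, 0)), 1L)
  expect_equal(median_energy_split(c(1, 1, 1, 1)), 2L)
  expect_error(median_energy_split(c(0, 0, 0)), "zero total energy")
  expect_warning(C <- median_energy_split(c(0, 0, 0, 5)), "clipped")
  expect_equal(C, 3L)

  # brute-force linear-scan oracle on random ESD vectors
  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    esd <- stats::rexp(n)
    total <- sum(esd)
    oracle <- NA
    acc <- 0
    for (k in seq_len(n)) {
      acc <- acc + esd[k]
      if (acc >= total / 2) { oracle <- k; break }
    }
    oracle <- min(oracle, n - 1)
    expect_equal(median_energy_split(esd), as.integer(oracle))
  }
})

test_that("ideal filtering splits, reconstructs, and is idempotent", {
  cn <- random_connectome(8, seed = 19)
  sp <- decompose_laplacian(normalized_laplacian(cn))
  C <- 3L
  U <- sp$eigenvectors

  # signal purely in the low band: decoupled vanishes
  Xl <- U[, 1:C] %*% matrix(rnorm(C * 5), C, 5)
  rownames(Xl) <- cn$node_ids
  f <- filter_signals(sp, C, parcellated_bold(Xl))
  expect_lt(max(abs(f$decoupled)), 1e-10)
  # and the complementary case
  Xh <- U[, (C + 1):8] %*% matrix(rnorm(5 * 5), 5, 5)
  rownames(Xh) <- cn$node_ids
  fh <- filter_signals(sp, C, parcellated_bold(Xh))
  expect_lt(max(abs(fh$coupled)), 1e-10)

  bold <- random_bold(cn, n_tr = 12, seed = 20)
  f <- filter_signals(sp, C, bold)
  expect_lt(max(abs(f$coupled + f$decoupled - bold$data)), 1e-10)
  # idempotence of the low-pass projector
  f2 <- filter_signals(sp, C, parcellated_bold(f$coupled))
  expect_lt(max(abs(f2$coupled - f$coupled)), 1e-9)

  sb <- graph_fourier_transform(sp, bold)
  expect_error(filter_signals(sp, sb, bold), "split_index unset")
})

test_that("coupling norms obey the 3-4-5 example and per-TR scaling", {
  coupled <- matrix(c(3, 4), 1, 2, dimnames = list("a", NULL))
  decoupled <- matrix(0, 1, 2, dimnames = list("a", NULL))
  p <- coupling_profile(coupled, decoupled, normalize = "none")
  expect_equal(unname(p$s_c), 5)
  expect_equal(unname(p$s_d), 0)
  p2 <- coupling_profile(coupled, decoupled)   # per_tr default
  expect_equal(unname(p2$s_c), 5 / sqrt(2))
  expect_error(coupling_profile(coupled, matrix(0, 2, 2)), "shape mismatch")
})

test_that("subject_coupling is deterministic and equals manual composition", {
  cn <- random_connectome(20, seed = 23)
  bold <- random_bold(cn, n_tr = 15, seed = 24)
  p1 <- subject_coupling(cn, bold)
  p2 <- subject_coupling(cn, bold)
  expect_identical(p1, p2)

  sp <- decompose_laplacian(normalized_laplacian(cn))
  sb <- graph_fourier_transform(sp, bold)
  C <- median_energy_split(sb)
  f <- filter_signals(sp, C, bold)
  manual <- coupling_profile(f$coupled, f$decoupled)
  expect_equal(p1$s_c, manual$s_c, tolerance = 1e-12)
  expect_equal(p1$s_d, manual$s_d, tolerance = 1e-12)
  expect_equal(attr(p1, "split_index"), C)
})

test_that("profiles are permutation-equivariant and weight-scale invariant", {
  cn <- random_connectome(12, seed = 29)
  bold <- random_bold(cn, n_tr = 10, seed = 30)
  p <- subject_coupling(cn, bold)

  perm <- sample(12)
  ids <- cn$node_ids[perm]
  cnp <- connectome(cn$weights[ids, ids], cn$network_of)
  boldp <- parcellated_bold(bold$data[ids, ])
  pp <- subject_coupling(cnp, boldp)
  expect_equal(pp$s_c[cn$node_ids], p$s_c, tolerance = 1e-9)
  expect_equal(pp$s_d[cn$node_ids], p$s_d, tolerance = 1e-9)

  cns <- connectome(cn$weights * 7.3, cn$network_of)
  ps <- subject_coupling(cns, bold)
  expect_equal(ps$s_c, p$s_c, tolerance = 1e-9)
  expect_equal(ps$s_d, p$s_d, tolerance = 1e-9)
})

test_that("group_mean split applies one common cut to every subject", {
  cfg <- small_cohort_config(seed = 41)
  ch <- generate_cohort(cfg)
  prof <- cohort_coupling(ch$connectomes, ch$bolds, split = "group_mean")
  C <- attr(prof, "split_index")
  expect_true(is.integer(C) && C >= 1)
  expect_true(all(vapply(prof, function(p) attr(p, "split_index"),
                         integer(1)) == C))
})
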