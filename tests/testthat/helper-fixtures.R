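# Shared fixture builders: everything is generated in code at test time.

# random connected weighted connectome over n nodes, two networks
random_connectome <- function(n, seed = 1, density = 0.6) {
  set.seed(seed)
  A <- matrix(0, n, n)
  w <- stats::runif(n * (n - 1) / 2)
  w[stats::runif(length(w)) > density] <- 0
  A[upper.tri(A)] <- w
  A <- A + t(A)
  # guarantee connectivity with a weighted ring
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (A[i, j] == 0) A[i, j] <- A[j, i] <- stats::runif(1, 0.2, 1)
  }
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  nets <- stats::setNames(rep(c("netA", "netB"), length.out = n), ids)
  connectome(A, nets)
}

# random bold over a connectome's nodes
random_bold <- function(cn, n_tr = 20, seed = 2) {
  set.seed(seed)
  X <- matrix(stats::rnorm(length(cn$node_ids) * n_tr),
              length(cn$node_ids), n_tr,
              dimnames = list(cn$node_ids, NULL))
  parcellated_bold(X)
}

# synthetic coupling profiles (no GSP involved) for stacking tests
fake_profiles <- function(subjects, n_nodes, seed = 3) {
  set.seed(seed)
  nodes <- sprintf("area%03d", seq_len(n_nodes))
  out <- lapply(subjects$subject_id, function(id) {
    structure(list(
      s_c = stats::setNames(abs(stats::rnorm(n_nodes, 1)), nodes),
      s_d = stats::setNames(abs(stats::rnorm(n_nodes, 1)), nodes),
      normalize = "per_tr"), class = "coupling_profile")
  })
  names(out) <- subjects$subject_id
  out
}

make_subjects <- function(n_per_group, seed = 4) {
  set.seed(seed)
  do.call(rbind, lapply(names(n_per_group), function(g) {
    n <- n_per_group[[g]]
    data.frame(subject_id = sprintf("%s%02d", g, seq_len(n)),
               age_years = stats::runif(n, 20, 49),
               group = g,
               mean_fd_mm = stats::rlnorm(n, log(0.08), 0.4),
               stringsAsFactors = FALSE)
  }))
}

# small simulated cohort for end-to-end tests
small_cohort_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_nodes = 24, n_networks = 12,
               n_per_group = c(athlete = 5, control = 4), n_trs = 30)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}
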