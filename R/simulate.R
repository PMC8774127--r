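# Synthetic cohort generator: weighted block-model connectomes and BOLD
# synthesized directly in the graph spectral domain, so that the planted
# coupling structure (which eigenmodes carry energy, and how that depends
# on age and group) is analytically controlled.

CA_NETWORKS <- c("visual1", "visual2", "somatomotor", "cinguloopercular",
                 "dorsalattention", "language", "frontoparietal",
                 "auditory", "default", "posteriormultimodal",
                 "ventralmultimodal", "orbitoaffective")

network_names <- function(n) {
  if (n <= length(CA_NETWORKS)) CA_NETWORKS[seq_len(n)]
  else c(CA_NETWORKS, sprintf("network%02d", seq_len(n - length(CA_NETWORKS)) +
                                length(CA_NETWORKS)))
}

#' Planted age-by-group coupling effect
#'
#' Describes the ground truth the simulator embeds: on eigenmodes supported
#' by the target networks, the low-band (coupled) spectral amplitude gains
#' `slope_sc_per_year` per year of age, and the high-band (decoupled)
#' amplitude gains `slope_sd_per_year`, separately per group.  Slopes are
#' fractional amplitude change per year (0.03 = 3%/year), applied around
#' the midpoint of the group's age range.  `baseline_low_high_ratio` is the
#' ratio of total low-band to high-band energy before any effect; `Inf`
#' concentrates all energy in the single lowest eigenmode.
#'
#' @param target_networks networks carrying the effect.
#' @param slope_sc_per_year,slope_sd_per_year named numeric per group.
#' @param baseline_low_high_ratio positive real (may be `Inf`).
#' @return list of class `"planted_effect"`.
#' @export
planted_effect <- function(target_networks = c("frontoparietal", "default"),
                           slope_sc_per_year = c(athlete = 0.1, control = 0),
                           slope_sd_per_year = c(athlete = 0, control = 0),
                           baseline_low_high_ratio = 2) {
  stopifnot(baseline_low_high_ratio > 0)
  structure(list(target_networks = target_networks,
                 slope_sc_per_year = slope_sc_per_year,
                 slope_sd_per_year = slope_sd_per_year,
                 baseline_low_high_ratio = baseline_low_high_ratio),
            class = "planted_effect")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 360 cortical areas in 12
#' intrinsic connectivity networks, 106-TR resting-state runs, and a
#' cohort of 19 athletes (23-45 years) and 14 controls (19-49 years;
#' the demographic table includes a 19-year-old control, so the lower
#' bound follows the table rather than the stated range).
#'
#' @param seed master seed; the whole cohort is a pure function of the
#'   config including this seed.
#' @param n_nodes,n_networks parcellation size and network count.
#' @param n_per_group named integer vector of subjects per group (each
#'   >= 2).
#' @param age_range named list group -> c(min, max) years.
#' @param n_trs TRs per BOLD run.
#' @param within_block_weight_mean,between_block_weight_mean mean edge
#'   weight inside vs between network blocks (within > between > 0).
#' @param effect a [planted_effect()].
#' @param noise_sd standard deviation of white observation noise added to
#'   the BOLD signal (signal spectral amplitudes are O(1)).
#' @param fd_meanlog,fd_sdlog lognormal parameters for simulated mean
#'   framewise displacement (defaults give typical low-motion values
#'   around 0.08 mm).
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_nodes = 360L,
                              n_networks = 12L,
                              n_per_group = c(athlete = 19L, control = 14L),
                              age_range = list(athlete = c(23, 45),
                                               control = c(19, 49)),
                              n_trs = 106L,
                              within_block_weight_mean = 1,
                              between_block_weight_mean = 0.2,
                              effect = planted_effect(),
                              noise_sd = 0.2,
                              fd_meanlog = log(0.08),
                              fd_sdlog = 0.4) {
  stopifnot(n_nodes >= 2, n_networks >= 1, n_networks <= n_nodes,
            n_trs >= 2, noise_sd >= 0)
  if (!(within_block_weight_mean > between_block_weight_mean &&
        between_block_weight_mean > 0))
    stop("need within_block_weight_mean > between_block_weight_mean > 0",
         call. = FALSE)
  if (any(n_per_group < 2))
    stop("each group needs at least 2 subjects", call. = FALSE)
  if (!setequal(names(n_per_group), names(age_range)))
    stop("n_per_group and age_range must name the same groups", call. = FALSE)
  nets <- network_names(n_networks)
  if (!all(effect$target_networks %in% nets))
    stop("target_networks outside the generated networks: ",
         paste(setdiff(effect$target_networks, nets), collapse = ", "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 n_networks = as.integer(n_networks),
                 n_per_group = n_per_group, age_range = age_range,
                 n_trs = as.integer(n_trs),
                 within_block_weight_mean = within_block_weight_mean,
                 between_block_weight_mean = between_block_weight_mean,
                 effect = effect, noise_sd = noise_sd,
                 fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
                 networks = nets),
            class = "simulation_config")
}

# Even partition of nodes into network blocks (remainder spread over the
# first blocks); returns named character vector node_id -> network.
block_labels <- function(config) {
  sizes <- rep(config$n_nodes %/% config$n_networks, config$n_networks)
  extra <- config$n_nodes %% config$n_networks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ids <- sprintf("area%03d", seq_len(config$n_nodes))
  stats::setNames(rep(config$networks, times = sizes), ids)
}

# connected components of a nonnegative adjacency matrix (plain BFS)
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Generate one block-model connectome
#'
#' Nodes are partitioned evenly into `n_networks` blocks; edge weights are
#' drawn from gamma distributions (shape 4) whose means are the configured
#' within-/between-block means, giving strictly positive continuous
#' weights with community structure, as in streamline counts normalized by
#' fiber length.  If the realized graph is disconnected (impossible with
#' gamma weights, but guarded for custom edits), minimal bridging edges at
#' the between-block mean are added and recorded in the `bridged`
#' attribute.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for this draw (defaults to `config$seed`).
#' @return a [connectome()].
#' @export
generate_connectome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  labels <- block_labels(config)
  n <- config$n_nodes
  blk <- match(labels, config$networks)
  same <- outer(blk, blk, `==`)
  up <- upper.tri(same)
  m <- ifelse(same[up], config$within_block_weight_mean,
              config$between_block_weight_mean)
  w <- stats::rgamma(length(m), shape = 4, rate = 4 / m)
  A <- matrix(0, n, n, dimnames = list(names(labels), names(labels)))
  A[up] <- w
  A <- A + t(A)
  comp <- graph_components(A)
  bridged <- 0L
  if (max(comp) > 1L) {
    for (k in 2:max(comp)) {
      i <- which(comp == 1L)[1]
      j <- which(comp == k)[1]
      A[i, j] <- A[j, i] <- config$between_block_weight_mean
      bridged <- bridged + 1L
    }
    message("connected ", bridged, " component(s) via bridging edges")
  }
  cn <- connectome(A, labels)
  attr(cn, "bridged") <- bridged
  cn
}

# Per-eigenmode baseline spectral sd implementing the configured low/high
# band energy ratio R via geometric decay: esd_k ~ rho^(k-1) with
# rho = R^(-2/N), so sum(low half) / sum(high half) = R.  R = Inf gives
# rho = 0: all energy in the lowest eigenmode.
baseline_spectral_sd <- function(N, ratio) {
  if (is.infinite(ratio)) return(c(1, rep(0, N - 1)))
  rho <- ratio^(-2 / N)
  sqrt(rho^(seq_len(N) - 1))
}

#' Generate one subject's BOLD run in the spectral domain
#'
#' Graph Fourier coefficients for each TR are drawn as independent
#' zero-mean normals.  Their per-mode standard deviation follows the
#' geometric baseline profile set by `baseline_low_high_ratio`, modulated
#' by the planted effect: for eigenmode `k` with support
#' `w_k = sum over target-network nodes of U[i,k]^2`, the amplitude is
#' multiplied by `1 + slope * (age - midpoint of group age range) * w_k`
#' (floored at 0.05), using `slope_sc_per_year` on the low half of the
#' modes and `slope_sd_per_year` on the high half.  The coefficients are
#' inverse-transformed to node space and white noise of sd `noise_sd` is
#' added.
#'
#' @param cn the subject's [connectome()].
#' @param subject one-row data.frame with `age_years` and `group` (and
#'   `subject_id`).
#' @param config a [simulation_config()].
#' @param seed integer seed for this draw.
#' @return a [parcellated_bold()] (TR = 3 s).
#' @export
generate_subject_bold <- function(cn, subject, config, seed = config$seed) {
  stopifnot(inherits(cn, "connectome"),
            inherits(config, "simulation_config"))
  spec <- decompose_laplacian(normalized_laplacian(cn))
  sd_k <- subject_spectral_sd(spec, subject, config)
  N <- length(sd_k)
  set.seed(seed)
  coef <- matrix(stats::rnorm(N * config$n_trs), N, config$n_trs) * sd_k
  X <- spec$eigenvectors %*% coef
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd),
                    nrow(X), ncol(X))
  rownames(X) <- cn$node_ids
  parcellated_bold(X, tr_seconds = 3)
}

# per-mode spectral sd for one subject (baseline profile x planted effect)
subject_spectral_sd <- function(spec, subject, config) {
  N <- length(spec$eigenvalues)
  eff <- config$effect
  sd_k <- baseline_spectral_sd(N, eff$baseline_low_high_ratio)
  grp <- subject$group
  sc_slope <- eff$slope_sc_per_year[[grp]] %||% 0
  sd_slope <- eff$slope_sd_per_year[[grp]] %||% 0
  if ((sc_slope != 0 || sd_slope != 0) && length(eff$target_networks)) {
    net <- config_network_of(spec, config)
    target_nodes <- names(net)[net %in% eff$target_networks]
    w <- colSums(spec$eigenvectors[target_nodes, , drop = FALSE]^2)
    mid <- mean(config$age_range[[grp]])
    dage <- subject$age_years - mid
    low <- seq_len(floor(N / 2))
    mult <- rep(1, N)
    mult[low] <- 1 + sc_slope * dage * w[low]
    mult[-low] <- 1 + sd_slope * dage * w[-low]
    sd_k <- sd_k * pmax(mult, 0.05)
  }
  sd_k
}

# network assignment for the spectrum's nodes under this config
config_network_of <- function(spec, config) {
  labels <- block_labels(config)
  labels[spec$node_ids]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort
#'
#' Draws subject metadata (ages uniform within each group's range, mean FD
#' lognormal), one connectome and one BOLD run per subject, and a ground
#' truth table recording each subject's expected low/high band energy per
#' network (computed analytically from the planted spectral profile, for
#' recovery tests).  One master seed derives independent per-subject
#' substreams, so the entire cohort is a pure function of the config.
#'
#' @param config a [simulation_config()].
#' @return list of class `"synthetic_cohort"` with elements `subjects`
#'   (data.frame), `connectomes` (named list), `bolds` (named list),
#'   `network_of` (named character), `ground_truth` (data.frame), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  subjects <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    rng <- config$age_range[[g]]
    data.frame(
      subject_id = sprintf("%s%02d", g, seq_len(n)),
      age_years = stats::runif(n, rng[1], rng[2]),
      group = g,
      mean_fd_mm = stats::rlnorm(n, config$fd_meanlog, config$fd_sdlog),
      stringsAsFactors = FALSE)
  }))
  rownames(subjects) <- NULL

  connectomes <- list()
  bolds <- list()
  gt <- list()
  half <- floor(config$n_nodes / 2)
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    cn <- generate_connectome(config, seed = config$seed + 1000L + i)
    bold <- generate_subject_bold(cn, s, config,
                                  seed = config$seed + 200000L + i)
    connectomes[[s$subject_id]] <- cn
    bolds[[s$subject_id]] <- bold

    spec <- decompose_laplacian(normalized_laplacian(cn))
    sd_k <- subject_spectral_sd(spec, s, config)
    # expected node-band energy: E[x_i,band^2] = sum_k in band U_ik^2 var_k
    U2 <- spec$eigenvectors^2
    var_k <- sd_k^2
    e_low <- U2[, seq_len(half), drop = FALSE] %*% var_k[seq_len(half)] +
      config$noise_sd^2 * half / config$n_nodes
    e_high <- U2[, -seq_len(half), drop = FALSE] %*% var_k[-seq_len(half)] +
      config$noise_sd^2 * (config$n_nodes - half) / config$n_nodes
    net <- cn$network_of
    gt[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id,
      network = config$networks,
      exp_low_energy = as.numeric(tapply(e_low, net, sum)[config$networks]),
      exp_high_energy = as.numeric(tapply(e_high, net, sum)[config$networks]),
      stringsAsFactors = FALSE)
  }
  ground_truth <- do.call(rbind, gt)
  rownames(ground_truth) <- NULL
  ground_truth$exp_ratio <-
    ground_truth$exp_low_energy / ground_truth$exp_high_energy

  structure(list(subjects = subjects, connectomes = connectomes,
                 bolds = bolds, network_of = block_labels(config),
                 ground_truth = ground_truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", nrow(x$subjects), " subjects (",
      paste(sprintf("%s=%d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      "), ", x$config$n_nodes, " nodes, ", x$config$n_trs, " TRs\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic cohort to a directory as the standard file set
#'
#' Produces `labels.tsv`, `subjects.tsv`, `ground_truth.tsv`, and per
#' subject `<id>_connectome.tsv` / `<id>_bold.tsv`, readable by the
#' package's readers.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(cohort$network_of, file.path(dir, "labels.tsv"))
  write_subjects(cohort$subjects, file.path(dir, "subjects.tsv"))
  utils::write.table(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$connectomes)) {
    write_connectome(cohort$connectomes[[id]],
                     file.path(dir, paste0(id, "_connectome.tsv")))
    write_timeseries(cohort$bolds[[id]],
                     file.path(dir, paste0(id, "_bold.tsv")))
  }
  invisible(dir)
}
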