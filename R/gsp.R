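# Graph signal processing core: Laplacian spectrum of the structural
# connectome, graph Fourier transform of BOLD, median energy split, ideal
# low/high-pass filtering, and per-area coupling/decoupling norms.

#' Symmetric normalized graph Laplacian of a connectome
#'
#' `L = I - D^(-1/2) A D^(-1/2)` with `D = diag(rowSums(A))`.  The spectrum
#' of this operator lies in `[0, 2]`; its eigenvectors are the graph
#' harmonics used as the Fourier basis for BOLD signals.  Degree
#' normalization makes `L` invariant to a global rescaling of the edge
#' weights.
#'
#' @param cn a [connectome()].
#' @return symmetric numeric matrix with the connectome's node dimnames.
#' @export
normalized_laplacian <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  A <- cn$weights
  deg <- rowSums(A)
  if (any(deg <= 0)) {
    bad <- cn$node_ids[deg <= 0]
    stop("isolated node(s) with zero degree: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  s <- 1 / sqrt(deg)
  L <- -(s %o% s) * A
  diag(L) <- diag(L) + 1
  L <- (L + t(L)) / 2   # kill rounding asymmetry
  L
}

#' Eigendecomposition of a graph Laplacian
#'
#' Full symmetric eigendecomposition `L = U diag(lambda) U'`, eigenvalues
#' sorted ascending so that column `k` of `U` is the k-th graph harmonic:
#' small eigenvalues correspond to spatially smooth ("low graph frequency")
#' patterns aligned with structure, large eigenvalues to rough patterns.
#' Each eigenvector's sign is fixed so that its first component exceeding
#' 1e-10 in magnitude is positive, which makes downstream saliences
#' reproducible across linear-algebra backends.
#'
#' @param L symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @return object of class `"graph_spectrum"`: list with `eigenvalues`
#'   (ascending), `eigenvectors` (orthonormal columns), `laplacian`, and
#'   `node_ids` (dimnames of `L`, if any).
#' @export
decompose_laplacian <- function(L) {
  if (!is.matrix(L) || nrow(L) != ncol(L))
    stop("Laplacian must be a square matrix", call. = FALSE)
  if (max(abs(L - t(L))) > 1e-8)
    stop("asymmetric Laplacian", call. = FALSE)
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  idx <- order(e$values)            # eigen() returns descending
  lambda <- e$values[idx]
  U <- e$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(U))) {
    lead <- which(abs(U[, k]) > 1e-10)[1]
    if (!is.na(lead) && U[lead, k] < 0) U[, k] <- -U[, k]
  }
  rownames(U) <- rownames(L)
  structure(
    list(eigenvalues = lambda, eigenvectors = U, laplacian = L,
         node_ids = rownames(L)),
    class = "graph_spectrum")
}

#' @export
print.graph_spectrum <- function(x, ...) {
  cat("graph_spectrum: ", length(x$eigenvalues), " eigenmodes, lambda in [",
      format(min(x$eigenvalues), digits = 3), ", ",
      format(max(x$eigenvalues), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Graph Fourier transform of a BOLD run
#'
#' Projects each TR of the parcellated signal onto the graph harmonics:
#' `coefficients = U' X`.  The energy spectral density (ESD) of eigenmode
#' `k` is the mean over TRs of its squared coefficient.  Parseval's
#' identity holds: total energy is identical in node and spectral domain.
#'
#' @param spectrum a `graph_spectrum`.
#' @param bold a [parcellated_bold()] over the same nodes (re-ordered to
#'   the spectrum's node order if needed).
#' @return object of class `"spectral_bold"`: list with `coefficients`
#'   (modes x TRs), `esd`, and `split_index` (`NULL` until
#'   [median_energy_split()] is applied).
#' @export
graph_fourier_transform <- function(spectrum, bold) {
  stopifnot(inherits(spectrum, "graph_spectrum"),
            inherits(bold, "parcellated_bold"))
  X <- bold$data
  if (!is.null(spectrum$node_ids)) {
    if (!setequal(rownames(X), spectrum$node_ids))
      stop("node ids of timeseries and spectrum differ", call. = FALSE)
    X <- X[spectrum$node_ids, , drop = FALSE]
  } else if (nrow(X) != nrow(spectrum$eigenvectors)) {
    stop("node count mismatch", call. = FALSE)
  }
  coef <- crossprod(spectrum$eigenvectors, X)
  structure(
    list(coefficients = coef,
         esd = rowMeans(coef^2),
         split_index = NULL),
    class = "spectral_bold")
}

#' Median split of the energy spectral density
#'
#' Returns the cut `C`: the smallest number of ascending eigenmodes whose
#' cumulative ESD reaches at least half the total.  Modes `1..C` form the
#' low-frequency (coupled) band, modes `C+1..N` the high-frequency
#' (decoupled) band.  `C` is clipped to `N - 1` (with a warning) when all
#' energy is low-frequency, so the high band is never empty.
#'
#' @param spectral a `spectral_bold` (or a bare non-negative ESD vector).
#' @return integer split index `C` in `[1, N - 1]`.
#' @export
median_energy_split <- function(spectral) {
  esd <- if (inherits(spectral, "spectral_bold")) spectral$esd else spectral
  if (any(esd < 0)) stop("negative ESD", call. = FALSE)
  total <- sum(esd)
  if (total <= 0) stop("zero total energy", call. = FALSE)
  C <- which(cumsum(esd) >= total / 2)[1]
  if (C >= length(esd)) {
    warning("all energy at the highest eigenmode; split clipped to N - 1",
            call. = FALSE)
    C <- length(esd) - 1L
  }
  as.integer(C)
}

#' Ideal low/high-pass graph filtering
#'
#' Splits the signal into a structurally coupled part, its projection onto
#' the low band (`U_low U_low' X`, eigenmodes `1..C`), and a decoupled
#' part, the projection onto the complementary high band.  The two
#' projectors are orthogonal complements, so `coupled + decoupled == X`
#' and each part is idempotent under re-filtering.
#'
#' @param spectrum a `graph_spectrum`.
#' @param C split index from [median_energy_split()] (or a `spectral_bold`
#'   whose `split_index` is set).
#' @param bold a [parcellated_bold()] aligned with the spectrum.
#' @return list with matrices `coupled` and `decoupled` (nodes x TRs).
#' @export
filter_signals <- function(spectrum, C, bold) {
  stopifnot(inherits(spectrum, "graph_spectrum"))
  if (inherits(C, "spectral_bold")) {
    if (is.null(C$split_index))
      stop("split_index unset; run median_energy_split() first",
           call. = FALSE)
    C <- C$split_index
  }
  N <- length(spectrum$eigenvalues)
  C <- as.integer(C)
  if (is.na(C) || C < 1 || C > N - 1)
    stop("split index must be in [1, N - 1]", call. = FALSE)
  X <- bold$data
  if (!is.null(spectrum$node_ids)) X <- X[spectrum$node_ids, , drop = FALSE]
  U <- spectrum$eigenvectors
  coef <- crossprod(U, X)
  low <- seq_len(C)
  coupled <- U[, low, drop = FALSE] %*% coef[low, , drop = FALSE]
  decoupled <- U[, -low, drop = FALSE] %*% coef[-low, , drop = FALSE]
  dimnames(coupled) <- dimnames(decoupled) <- dimnames(X)
  list(coupled = coupled, decoupled = decoupled)
}

#' Per-area structural coupling and decoupling
#'
#' `S_C[i]` is the temporal L2 norm of the low-pass-filtered signal at
#' area `i`, `S_D[i]` the norm of the high-pass-filtered signal.  Because
#' the band projectors are orthogonal complements, the summed coupled and
#' decoupled energies equal the total signal energy (an area's own
#' `S_C[i]^2 + S_D[i]^2` can differ from its signal energy, since the
#' projectors are orthogonal over areas, not over time at one area).  With
#' `normalize = "per_tr"` (default) both norms are divided by `sqrt(TRs)`,
#' making values comparable across scan lengths.
#'
#' @param coupled,decoupled filtered matrices from [filter_signals()].
#' @param normalize `"per_tr"` or `"none"`.
#' @return object of class `"coupling_profile"`: list with named numeric
#'   vectors `s_c` and `s_d` and the `normalize` mode used.
#' @export
coupling_profile <- function(coupled, decoupled,
                             normalize = c("per_tr", "none")) {
  normalize <- match.arg(normalize)
  if (!identical(dim(coupled), dim(decoupled)))
    stop("shape mismatch between coupled and decoupled", call. = FALSE)
  s_c <- sqrt(rowSums(coupled^2))
  s_d <- sqrt(rowSums(decoupled^2))
  if (normalize == "per_tr") {
    s_c <- s_c / sqrt(ncol(coupled))
    s_d <- s_d / sqrt(ncol(coupled))
  }
  names(s_c) <- names(s_d) <- rownames(coupled)
  structure(list(s_c = s_c, s_d = s_d, normalize = normalize),
            class = "coupling_profile")
}

#' Coupling profile of one subject
#'
#' Chains the full per-subject decomposition: normalized Laplacian ->
#' eigendecomposition -> graph Fourier transform -> median energy split ->
#' ideal filtering -> temporal norms.
#'
#' @param cn the subject's [connectome()].
#' @param bold the subject's [parcellated_bold()].
#' @param normalize passed to [coupling_profile()].
#' @param split_index optional fixed cut; by default the subject's own
#'   median energy split is used (see [cohort_coupling()] for the
#'   cohort-mean alternative).
#' @return a `coupling_profile`; attributes `split_index` and
#'   `total_energy` record the cut and the signal energy.
#' @export
subject_coupling <- function(cn, bold, normalize = c("per_tr", "none"),
                             split_index = NULL) {
  normalize <- match.arg(normalize)
  bold <- align_bold(bold, cn)
  spec <- decompose_laplacian(normalized_laplacian(cn))
  sb <- graph_fourier_transform(spec, bold)
  C <- if (is.null(split_index)) median_energy_split(sb)
       else as.integer(split_index)
  filt <- filter_signals(spec, C, bold)
  prof <- coupling_profile(filt$coupled, filt$decoupled, normalize)
  attr(prof, "split_index") <- C
  attr(prof, "total_energy") <- sum(sb$esd) * ncol(bold$data)
  prof
}

#' Coupling profiles for a whole cohort
#'
#' Computes a [subject_coupling()] profile per subject.  With
#' `split = "subject"` (default) each subject uses their own median energy
#' split; with `split = "group_mean"` one cut is derived from the
#' cohort-average energy spectral density and applied to every subject.
#'
#' @param connectomes named list of [connectome()] objects (by subject id).
#' @param bolds named list of [parcellated_bold()] objects (same names).
#' @param split `"subject"` or `"group_mean"`.
#' @param normalize passed on to [coupling_profile()].
#' @return named list of `coupling_profile`s; attribute `split_index`
#'   gives the common cut when `split = "group_mean"`.
#' @export
cohort_coupling <- function(connectomes, bolds,
                            split = c("subject", "group_mean"),
                            normalize = c("per_tr", "none")) {
  split <- match.arg(split)
  normalize <- match.arg(normalize)
  ids <- names(connectomes)
  if (!setequal(ids, names(bolds)))
    stop("connectome and timeseries subject ids differ", call. = FALSE)
  common_C <- NULL
  if (split == "group_mean") {
    esds <- lapply(ids, function(s) {
      spec <- decompose_laplacian(normalized_laplacian(connectomes[[s]]))
      graph_fourier_transform(spec, align_bold(bolds[[s]],
                                               connectomes[[s]]))$esd
    })
    common_C <- median_energy_split(Reduce(`+`, esds) / length(esds))
  }
  out <- lapply(ids, function(s)
    subject_coupling(connectomes[[s]], bolds[[s]], normalize = normalize,
                     split_index = common_C))
  names(out) <- ids
  if (!is.null(common_C)) attr(out, "split_index") <- common_C
  out
}
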