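# Global structural metrics: least-squares superposition RMSD, per-residue
# RMSF about the time-average structure, gromos (greedy neighbour-count)
# RMSD clustering, and block-standard-error convergence curves.

#' Superposition RMSD between two frames
#'
#' Minimal least-squares RMSD after optimal rigid-body superposition
#' (Kabsch rotation + translation), mass-unweighted.
#'
#' @param frameA,frameB `n x 3` coordinate matrices, or [rna_trajectory]
#'   objects combined with `framesA`/`framesB` indices.
#' @param selection optional atom index vector applied to both frames.
#' @param framesA,framesB frame indices when trajectories are supplied.
#' @return RMSD in Angstrom (`>= 0`).
#' @export
kabsch_rmsd <- function(frameA, frameB, selection = NULL, framesA = 1L,
                        framesB = 1L) {
  if (inherits(frameA, "rna_trajectory")) frameA <- get_frame(frameA, framesA)
  if (inherits(frameB, "rna_trajectory")) frameB <- get_frame(frameB, framesB)
  if (!is.null(selection)) {
    frameA <- frameA[selection, , drop = FALSE]
    frameB <- frameB[selection, , drop = FALSE]
  }
  if (nrow(frameA) == 0) stop("empty selection")
  if (nrow(frameA) != nrow(frameB)) stop("selection atom counts differ")
  fit <- kabsch_fit(frameA, frameB)
  rmsd_xyz(kabsch_apply(frameA, fit), frameB)
}

#' RMSD of every frame to a reference frame
#'
#' @param traj an [rna_trajectory].
#' @param ref reference frame index (default: first frame, i.e. the
#'   starting structure).
#' @param selection optional atom indices (default: all heavy atoms).
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_timeseries <- function(traj, ref = 1L, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(traj)
  refm <- get_frame(traj, ref)[selection, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f)
    kabsch_rmsd(get_frame(traj, f)[selection, , drop = FALSE], refm), 0)
}

# superpose all frames onto the time-average structure (one iteration):
# first fit every frame to the first frame, average, then refit to the mean
superpose_to_mean <- function(traj, selection) {
  nf <- n_frames(traj)
  ref <- get_frame(traj, 1)[selection, , drop = FALSE]
  fitted <- lapply(seq_len(nf), function(f) {
    m <- get_frame(traj, f)[selection, , drop = FALSE]
    kabsch_apply(m, kabsch_fit(m, ref))
  })
  avg <- Reduce(`+`, fitted) / nf
  lapply(fitted, function(m) kabsch_apply(m, kabsch_fit(m, avg)))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the average structure (single refinement
#' pass); the RMSF of a residue is the root mean square deviation of its
#' heavy atoms from their time-average positions, mass-unweighted.
#'
#' @param traj an [rna_trajectory] with at least two frames.
#' @param selection atom indices (default: all heavy atoms).
#' @param fit superpose frames onto the average structure first (set to
#'   `FALSE` for pre-aligned trajectories).
#' @return data frame `resno`, `label`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, fit = TRUE) {
  if (n_frames(traj) < 2) stop("RMSF requires at least two frames")
  if (is.null(selection)) selection <- select_atoms(traj)
  fitted <- if (fit) superpose_to_mean(traj, selection)
            else lapply(seq_len(n_frames(traj)), function(f)
              get_frame(traj, f)[selection, , drop = FALSE])
  nf <- length(fitted)
  avg <- Reduce(`+`, fitted) / nf
  dev2 <- Reduce(`+`, lapply(fitted, function(m) rowSums((m - avg)^2))) / nf
  tp <- traj$topology[selection, ]
  agg <- tapply(dev2, tp$resno, mean)
  resno <- as.integer(names(agg))
  data.frame(resno = resno,
             label = tp$label[match(resno, tp$resno)],
             rmsf = sqrt(as.numeric(agg)))
}

#' Pairwise superposition RMSD matrix
#'
#' @param traj an [rna_trajectory].
#' @param selection atom indices (default: all heavy atoms).
#' @param frames frame indices (default all).
#' @return symmetric matrix of RMSD values (Angstrom).
#' @export
pairwise_rmsd <- function(traj, selection = NULL, frames = NULL) {
  if (is.null(selection)) selection <- select_atoms(traj)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  mats <- lapply(frames, function(f)
    get_frame(traj, f)[selection, , drop = FALSE])
  n <- length(mats)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    fit <- kabsch_fit(mats[[i]], mats[[j]])
    M[i, j] <- M[j, i] <- rmsd_xyz(kabsch_apply(mats[[i]], fit), mats[[j]])
  }
  M
}

#' gromos RMSD clustering
#'
#' Greedy neighbour-count clustering: the structure with the most
#' neighbours within `cutoff` (pairwise superposition RMSD) becomes a
#' cluster centre, it and its neighbours are removed, and the procedure
#' repeats.  Ties on neighbour count are broken by the lowest frame index.
#'
#' @param traj an [rna_trajectory] (or a precomputed RMSD matrix).
#' @param cutoff RMSD criterion (Angstrom, > 0).
#' @param selection atom indices (default: all heavy atoms).
#' @param stride keep every `stride`-th frame.
#' @return object of class `cluster_result`: list with `cutoff`, `frames`
#'   (analysed frame indices), `assignments` (cluster id per analysed
#'   frame), `centers` (frame index of each cluster centre), `sizes`.
#' @export
gromos_cluster <- function(traj, cutoff, selection = NULL, stride = 1L) {
  stopifnot(cutoff > 0)
  if (is.matrix(traj)) {
    M <- traj
    frames <- seq_len(nrow(M))
  } else {
    if (n_frames(traj) == 0) stop("empty trajectory")
    frames <- seq(1L, n_frames(traj), by = stride)
    M <- pairwise_rmsd(traj, selection, frames)
  }
  n <- nrow(M)
  remaining <- seq_len(n)
  assignments <- integer(n)
  centers <- integer(0)
  cl <- 0L
  while (length(remaining) > 0) {
    cl <- cl + 1L
    sub <- M[remaining, remaining, drop = FALSE]
    nb <- rowSums(sub <= cutoff)     # includes self
    pick <- remaining[which.max(nb)] # which.max takes the first (lowest) tie
    members <- remaining[sub[match(pick, remaining), ] <= cutoff]
    assignments[members] <- cl
    centers[cl] <- frames[pick]
    remaining <- setdiff(remaining, members)
  }
  sizes <- as.integer(table(assignments))
  structure(list(cutoff = cutoff, frames = frames,
                 assignments = assignments, centers = centers,
                 sizes = sizes),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$sizes), " clusters at cutoff ",
      x$cutoff, " A over ", length(x$frames), " frames\n", sep = "")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Block-standard-error convergence curve
#'
#' For block sizes `m` (powers of two up to `N/4` by default) the series is
#' cut into `floor(N/m)` non-overlapping blocks and
#' `BSE(m) = sd(block means) / sqrt(n_blocks)`.  For a converged, decorrelated
#' series the curve rises monotonically and plateaus near the standard
#' deviation of the observable divided by the square root of the number of
#' independent blocks.
#'
#' @param series numeric vector (length >= 4).
#' @param block_sizes block lengths; default `2^k` up to `length(series)/4`.
#' @return object of class `bse_curve`: data frame `block_size`, `n_blocks`,
#'   `bse`, with attributes `n` and `sd` of the raw series.
#' @export
block_standard_error <- function(series, block_sizes = NULL) {
  N <- length(series)
  if (N < 4) stop("series too short for block averaging")
  if (is.null(block_sizes))
    block_sizes <- 2^(0:floor(log2(N / 4)))
  block_sizes <- sort(unique(as.integer(block_sizes)))
  if (any(block_sizes < 1 | block_sizes > N / 2))
    stop("block sizes must lie in [1, N/2]")
  out <- data.frame(block_size = block_sizes, n_blocks = NA_integer_,
                    bse = NA_real_)
  for (k in seq_along(block_sizes)) {
    m <- block_sizes[k]
    nb <- floor(N / m)
    means <- colMeans(matrix(series[seq_len(nb * m)], nrow = m))
    out$n_blocks[k] <- nb
    out$bse[k] <- sd(means) / sqrt(nb)
  }
  structure(out, class = c("bse_curve", "data.frame"),
            n = N, sd = sd(series))
}

#' Analytic block-average curve for a two-exponential autocorrelation
#'
#' Fits `BSE(m)` assuming the autocorrelation function of the series is a
#' sum of two exponentials `A1 exp(-k/tau1) + (1-A1) exp(-k/tau2)`; the
#' model curve is the exact block-mean standard error implied by that
#' autocorrelation.  Used to judge whether blocks are longer than the
#' correlation time.
#'
#' @param bse a [block_standard_error()] result.
#' @return list with the fitted parameters (`A1`, `tau1`, `tau2`), the
#'   implied correlation-time estimate and the fitted curve.
#' @export
fit_bse_two_exp <- function(bse) {
  N <- attr(bse, "n"); s2 <- attr(bse, "sd")^2
  model_bse <- function(A1, tau1, tau2, m) {
    vapply(m, function(mm) {
      k <- seq_len(mm - 1)
      rho <- if (mm > 1)
        A1 * exp(-k / tau1) + (1 - A1) * exp(-k / tau2) else numeric(0)
      varblock <- s2 / mm * (1 + 2 * sum((1 - k / mm) * rho))
      sqrt(varblock / floor(N / mm))
    }, 0)
  }
  obj <- function(p) {
    A1 <- 1 / (1 + exp(-p[1])); tau1 <- exp(p[2]); tau2 <- exp(p[3])
    sum((model_bse(A1, tau1, tau2, bse$block_size) - bse$bse)^2)
  }
  fit <- optim(c(0, 0, log(5)), obj, control = list(maxit = 2000))
  A1 <- 1 / (1 + exp(-fit$par[1]))
  tau1 <- exp(fit$par[2]); tau2 <- exp(fit$par[3])
  list(A1 = A1, tau1 = tau1, tau2 = tau2,
       tau_int = A1 * tau1 + (1 - A1) * tau2,
       fitted = model_bse(A1, tau1, tau2, bse$block_size),
       sse = fit$value)
}
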