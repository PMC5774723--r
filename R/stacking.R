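# Nucleobase stacking: geometric detection (six-membered-ring centroid
# distance and interplanar angle) and energy estimation as the sum of
# Coulomb and Lennard-Jones terms over the heavy atoms of the interacting
# nucleobases, with Lorentz-Berthelot-style combining and no cutoff.

.ff_env <- new.env(parent = emptyenv())

#' Nucleobase force-field parameters
#'
#' Reads a `(restype, atom, charge, epsilon, rmin_half)` CSV of per-atom
#' partial charges (e), Lennard-Jones well depths (kcal/mol) and Rmin/2
#' values (Angstrom) for the nucleobase heavy atoms.  The packaged default
#' set carries representative Amber-94-lineage values (the bsc0/chi-OL3
#' refits retain the base charges of that lineage); it is intended for the
#' synthetic fixtures and is user-overridable for production analyses.
#'
#' @param path CSV file; default: the packaged parameter set.
#' @return data frame with one row per (restype, atom).
#' @export
load_ff_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ff_env$default)) return(.ff_env$default)
    path <- system.file("extdata", "nucleobase_ff_params.csv",
                        package = "asitetools", mustWork = TRUE)
    .ff_env$default <- read.csv(path, stringsAsFactors = FALSE)
    return(.ff_env$default)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

ff_lookup <- function(params, restype, atoms) {
  idx <- match(paste(restype, atoms), paste(params$restype, params$atom))
  if (anyNA(idx))
    stop("missing force-field parameters for: ",
         paste(paste(restype, atoms)[is.na(idx)], collapse = ", "))
  params[idx, , drop = FALSE]
}

ring6_idx <- function(traj, resno) {
  tp <- traj$topology
  which(tp$resno == resno & tp$elety %in% RING6_ATOMS)
}

plane_normal_of <- function(xyz, idx) {
  m <- xyz[idx, , drop = FALSE]
  sv <- svd(sweep(m, 2, colMeans(m)))
  sv$v[, 3]
}

#' Detect stacked nucleobase pairs in a frame
#'
#' Residue pairs whose six-membered-ring centroids are within
#' `max_centroid_dist` and whose base planes subtend at most `max_angle`
#' are reported as stacked; pairs linked by base-mediated hydrogen bonds
#' (e.g. Watson-Crick partners) are excluded.
#'
#' @param traj an [rna_trajectory].
#' @param frame frame index.
#' @param max_centroid_dist centroid criterion (Angstrom).
#' @param max_angle interplanar criterion (degrees).
#' @param hbonds optional precomputed [detect_hbonds()] table.
#' @return data frame `res_i`, `res_j`, `label_i`, `label_j`,
#'   `centroid_dist`, `plane_angle`.
#' @export
detect_stacked <- function(traj, frame = 1L, max_centroid_dist = 4.5,
                           max_angle = 30, hbonds = NULL) {
  xyz <- get_frame(traj, frame)
  tp <- traj$topology
  resnos <- unique(tp$resno[tp$restype %in% names(BASE_ATOMS)])
  cent <- t(vapply(resnos, function(rn)
    colMeans(xyz[ring6_idx(traj, rn), , drop = FALSE]), numeric(3)))
  nrms <- t(vapply(resnos, function(rn)
    plane_normal_of(xyz, ring6_idx(traj, rn)), numeric(3)))
  if (is.null(hbonds)) hbonds <- detect_hbonds(traj, frame)
  hb <- classifiable_bonds(hbonds, tp, default_edge_table())
  bonded <- unique(paste(pmin(hb$don_resno, hb$acc_resno),
                         pmax(hb$don_resno, hb$acc_resno)))
  out <- NULL
  for (a in seq_along(resnos)) for (b in seq_along(resnos)) {
    if (b <= a) next
    d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
    if (d > max_centroid_dist) next
    ang <- acos(min(1, abs(sum(nrms[a, ] * nrms[b, ])))) * 180 / pi
    if (ang > max_angle) next
    if (paste(resnos[a], resnos[b]) %in% bonded) next
    out <- rbind(out, data.frame(
      res_i = resnos[a], res_j = resnos[b],
      label_i = tp$label[match(resnos[a], tp$resno)],
      label_j = tp$label[match(resnos[b], tp$resno)],
      centroid_dist = d, plane_angle = ang, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(res_i = integer(), res_j = integer(),
                      label_i = character(), label_j = character(),
                      centroid_dist = numeric(), plane_angle = numeric())
  out
}

#' Stacking energy of a residue pair
#'
#' Sum of the Coulomb term (`k q_i q_j / r`, `k = 332.0636`
#' kcal A mol^-1 e^-2) and the Lennard-Jones term
#' (`eps_ij ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with
#' `eps_ij = sqrt(eps_i eps_j)` and `Rmin_ij = Rmin_i/2 + Rmin_j/2`) over
#' all heavy atoms of the two nucleobases, with no cutoff.
#'
#' @param traj an [rna_trajectory].
#' @param i,j residue labels or indices.
#' @param frame frame index.
#' @param params force-field table from [load_ff_params()].
#' @return list of class `stack_energy` with `coulomb`, `vdw`, `total`
#'   (kcal/mol).
#' @export
stack_energy <- function(traj, i, j, frame = 1L, params = load_ff_params()) {
  ri <- resolve_residue(traj, i); rj <- resolve_residue(traj, j)
  xyz <- get_frame(traj, frame)
  tp <- traj$topology
  idx_i <- base_heavy_idx(traj, ri); idx_j <- base_heavy_idx(traj, rj)
  pi_ <- ff_lookup(params, tp$restype[idx_i][1], tp$elety[idx_i])
  pj_ <- ff_lookup(params, tp$restype[idx_j][1], tp$elety[idx_j])
  A <- xyz[idx_i, , drop = FALSE]; B <- xyz[idx_j, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  coul <- .K_COULOMB * sum(outer(pi_$charge, pj_$charge) / r)
  epsij <- sqrt(outer(pi_$epsilon, pj_$epsilon))
  rmin <- outer(pi_$rmin_half, pj_$rmin_half, "+")
  s6 <- (rmin / r)^6
  vdw <- sum(epsij * (s6^2 - 2 * s6))
  structure(list(res_i = ri, res_j = rj, coulomb = coul, vdw = vdw,
                 total = coul + vdw),
            class = "stack_energy")
}

#' @export
print.stack_energy <- function(x, ...) {
  cat(sprintf("<stack_energy> %d:%d  coulomb %.3f  vdw %.3f  total %.3f kcal/mol\n",
              x$res_i, x$res_j, x$coulomb, x$vdw, x$total))
  invisible(x)
}

# per-frame stacked pairs with energies
frame_stack_energies <- function(traj, frame, params,
                                 max_centroid_dist = 4.5, max_angle = 30) {
  st <- detect_stacked(traj, frame, max_centroid_dist, max_angle)
  if (nrow(st) == 0) {
    st$coulomb <- numeric(0); st$vdw <- numeric(0); st$total <- numeric(0)
    return(st)
  }
  en <- lapply(seq_len(nrow(st)), function(k)
    stack_energy(traj, st$res_i[k], st$res_j[k], frame, params))
  st$coulomb <- vapply(en, `[[`, 0, "coulomb")
  st$vdw <- vapply(en, `[[`, 0, "vdw")
  st$total <- vapply(en, `[[`, 0, "total")
  st
}

#' Region-averaged stacking energy per nucleotide
#'
#' For each frame the stacking energies of all pairs touching the region are
#' summed with a 50/50 per-pair split between the partners (pairs internal
#' to the region therefore count once in full), divided by the number of
#' region residues, and the per-frame values are summarized as mean and
#' standard deviation across frames.
#'
#' @param traj an [rna_trajectory].
#' @param residues region residue labels or indices.
#' @param params force-field table.
#' @param frames frame indices (default all).
#' @return one-row data frame: means and standard deviations of the
#'   per-nucleotide Coulomb, van der Waals and total stacking energy.
#' @export
region_average <- function(traj, residues, params = load_ff_params(),
                           frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  region <- vapply(residues, function(r) resolve_residue(traj, r), 0L)
  per_frame <- vapply(frames, function(f) {
    st <- frame_stack_energies(traj, f, params)
    w <- (st$res_i %in% region) + (st$res_j %in% region)
    c(coulomb = sum(0.5 * w * st$coulomb),
      vdw = sum(0.5 * w * st$vdw),
      total = sum(0.5 * w * st$total)) / length(region)
  }, numeric(3))
  data.frame(
    n_residues = length(region), n_frames = length(frames),
    coulomb_mean = mean(per_frame["coulomb", ]),
    coulomb_sd = sd(per_frame["coulomb", ]),
    vdw_mean = mean(per_frame["vdw", ]),
    vdw_sd = sd(per_frame["vdw", ]),
    total_mean = mean(per_frame["total", ]),
    total_sd = sd(per_frame["total", ]))
}

#' Windowed total stacking-energy time series
#'
#' Frame-wise sum of the stacking energy over all detected stacked pairs
#' (each pair counted once), averaged over non-overlapping windows.
#'
#' @param traj an [rna_trajectory].
#' @param params force-field table.
#' @param window frames per window (>= 1).
#' @return data frame `window`, `frame_from`, `frame_to`, `coulomb`, `vdw`,
#'   `total` (window means, kcal/mol).
#' @export
stacking_timeseries <- function(traj, params = load_ff_params(), window = 1L) {
  stopifnot(window >= 1)
  nf <- n_frames(traj)
  per <- t(vapply(seq_len(nf), function(f) {
    st <- frame_stack_energies(traj, f, params)
    c(coulomb = sum(st$coulomb), vdw = sum(st$vdw), total = sum(st$total))
  }, numeric(3)))
  idx <- split(seq_len(nf), ceiling(seq_len(nf) / window))
  data.frame(window = seq_along(idx),
             frame_from = vapply(idx, min, 0L),
             frame_to = vapply(idx, max, 0L),
             coulomb = vapply(idx, function(ii) mean(per[ii, "coulomb"]), 0),
             vdw = vapply(idx, function(ii) mean(per[ii, "vdw"]), 0),
             total = vapply(idx, function(ii) mean(per[ii, "total"]), 0))
}
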