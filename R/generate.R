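# Synthetic trajectory generator: an idealized A-form duplex is assembled
# from the rigid nucleotide templates on a helical lattice (rise 2.81 A,
# twist 32.7 deg per step).  Reference pairs share a lattice level so their
# Watson-Crick hydrogen bonds are satisfied by construction; bulged
# (unpaired) residues are placed intra-helically at interpolated levels with
# a small radial offset.  Scheduled base flips rotate the nucleobase about
# its local backbone axis until the flip pseudo-dihedral hits the requested
# extra-helical angle, so the flip classifier recovers schedules exactly.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
      else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
  }
  force(code)
}

# per-residue helical lattice levels for both strands of a construct;
# unpaired residues interpolate between (or extrapolate beyond) the levels
# of their flanking reference pairs
helix_layout <- function(construct) {
  rp <- construct$reference_pairs[order(construct$reference_pairs[, 1]), ,
                                  drop = FALSE]
  if (any(diff(rp[, 2]) >= 0))
    stop("reference pairs must be strictly antiparallel (posB decreasing)")
  np <- nrow(rp)
  lev <- numeric(np)
  for (k in seq_len(np - 1)) {
    lev[k + 1] <- lev[k] + max(rp[k + 1, 1] - rp[k, 1], rp[k, 2] - rp[k + 1, 2])
  }
  level_of <- function(p, ppos, plev, decreasing = FALSE) {
    # ppos: paired positions in level order (increasing for A, decreasing B)
    s <- if (decreasing) -1 else 1
    sp <- s * ppos; x <- s * p
    if (x <= sp[1]) return(plev[1] - (sp[1] - x))
    if (x >= sp[length(sp)]) return(plev[length(sp)] + (x - sp[length(sp)]))
    k <- max(which(sp <= x))
    plev[k] + (plev[k + 1] - plev[k]) * (x - sp[k]) / (sp[k + 1] - sp[k])
  }
  la <- strand_letters(construct$strandA)
  lb <- strand_letters(construct$strandB)
  layout <- list()
  for (p in seq_along(la)) {
    k <- match(p, rp[, 1])
    paired <- !is.na(k)
    layout[[length(layout) + 1]] <- list(
      strand = "A", pos = p, restype = la[p], paired = paired,
      level = if (paired) lev[k] else level_of(p, rp[, 1], lev),
      pairtype = if (paired) paste0(la[p], lb[rp[k, 2]])
                 else paste0(la[p], WC_PARTNER[[la[p]]]),
      role = "X")
  }
  for (p in seq_along(lb)) {
    k <- match(p, rp[, 2])
    paired <- !is.na(k)
    layout[[length(layout) + 1]] <- list(
      strand = "B", pos = p, restype = lb[p], paired = paired,
      level = if (paired) lev[k]
              else level_of(p, rp[, 2], lev, decreasing = TRUE),
      pairtype = if (paired) paste0(la[rp[k, 1]], lb[p])
                 else paste0(WC_PARTNER[[lb[p]]], lb[p]),
      role = "Y")
  }
  layout
}

place_template <- function(tmpl, level, rise, twist, radial_offset = 0,
                           role = "X") {
  m <- tmpl
  if (radial_offset != 0) {
    dir <- if (role == "X") c(-1, 0, 0) else c(1, 0, 0)
    m <- sweep(m, 2, radial_offset * dir, "+")
  }
  sweep(m %*% t(rot_z(level * twist)), 2, c(0, 0, level * rise), "+")
}

strand_label <- function(strand_obj, pos, strand_id) {
  lab <- strand_obj$numbering[[pos]]
  if (lab == "ext") paste0("ext_", strand_id, pos) else lab
}

#' Generate an idealized A-form duplex frame
#'
#' Builds a single-frame trajectory of the construct on an A-form-like
#' helical lattice from the rigid nucleotide templates.  Every reference
#' Watson-Crick pair satisfies the hydrogen-bond criteria (donor-acceptor
#' distance below 3.5 A, acceptor-hydrogen-donor angle above 150 degrees) by
#' construction, consecutive intra-strand bases are stacked, and all
#' intra-helical bases have flip pseudo-dihedral angles within (-50, 50)
#' degrees.  Unpaired (bulge and dangling) residues are placed
#' intra-helically at lattice levels interpolated between their flanking
#' pairs, displaced radially outward by `bulge_offset` to keep their
#' hydrogen-bonding edges out of register with the paired residues.
#'
#' @param construct an [rna_construct].
#' @param rise helical rise per lattice level (Angstrom).
#' @param twist helical twist per lattice level (degrees).
#' @param bulge_offset radial displacement of unpaired residues (Angstrom).
#' @return an [rna_trajectory] with one frame.
#' @export
generate_duplex_frame <- function(construct, rise = 2.81, twist = 32.7,
                                  bulge_offset = 2.0) {
  layout <- helix_layout(construct)
  strands <- list(A = construct$strandA, B = construct$strandB)
  tp <- NULL; xyz <- NULL
  for (i in seq_along(layout)) {
    r <- layout[[i]]
    if (!r$restype %in% names(GLYCO_ATOM)) stop("unknown residue type: ", r$restype)
    tmpl <- template_nucleotide(r$pairtype, r$role)
    m <- place_template(tmpl, r$level, rise, twist,
                        radial_offset = if (r$paired) 0 else bulge_offset,
                        role = r$role)
    tp <- rbind(tp, data.frame(
      eleno = NA_integer_, elety = rownames(tmpl), restype = r$restype,
      resno = i, strand = r$strand, pos = r$pos,
      label = strand_label(strands[[r$strand]], r$pos, r$strand),
      element = element_of(rownames(tmpl)), stringsAsFactors = FALSE))
    xyz <- rbind(xyz, m)
  }
  tp$eleno <- seq_len(nrow(tp))
  rownames(xyz) <- NULL
  traj <- rna_trajectory(tp, array(xyz, c(nrow(xyz), 3, 1)))
  traj$construct <- construct
  traj
}

#' Base-flip schedule for the trajectory generator
#'
#' @param residue E. coli residue label (e.g. `"U1498"`).
#' @param fraction_out fraction of frames in the extra-helical state.
#' @param groove `"major"` (negative flip angles) or `"minor"` (positive).
#' @param states optional explicit logical vector (length `nframes`) of
#'   out-states overriding `fraction_out`.
#' @return object of class `flip_schedule`.
#' @export
flip_schedule <- function(residue, fraction_out, groove = c("major", "minor"),
                          states = NULL) {
  groove <- match.arg(groove)
  stopifnot(fraction_out >= 0, fraction_out <= 1)
  structure(list(residue = residue, fraction_out = fraction_out,
                 groove = groove, states = states),
            class = "flip_schedule")
}

schedule_states <- function(schedule, nframes) {
  if (!is.null(schedule$states)) {
    stopifnot(length(schedule$states) == nframes)
    return(as.logical(schedule$states))
  }
  nout <- round(schedule$fraction_out * nframes)
  # single flip event: the residue leaves the helix and stays out
  c(rep(FALSE, nframes - nout), rep(TRUE, nout))
}

# rotate the nucleobase of `resno` about its P -> next-P backbone axis so
# that the flip pseudo-dihedral equals `target` exactly
set_flip_angle <- function(xyz, traj, resno, target, ref) {
  pts <- pseudo_dihedral_points(traj, resno, ref, xyz = xyz)
  tpr <- traj$topology[traj$topology$resno == resno, ]
  keep <- tpr$elety %in% c(BASE_ATOMS[[tpr$restype[1]]],
                           BASE_HYDROGENS[[tpr$restype[1]]])
  base_idx <- tpr$eleno[keep]
  cur <- dihedral_angle(pts$i, pts$ii, pts$iii, pts$iv)
  axis <- pts$iii - pts$ii
  sense_probe <- apply_rot(xyz[base_idx, , drop = FALSE],
                           rot_axis(10, axis, pts$ii))
  com_probe <- colMeans(sense_probe[traj$topology$element[base_idx] != "H", ,
                                    drop = FALSE])
  probe <- dihedral_angle(com_probe, pts$ii, pts$iii, pts$iv)
  delta <- ((probe - cur + 180) %% 360) - 180
  sense <- if (delta >= 0) 1 else -1
  alpha <- sense * (((target - cur + 180) %% 360) - 180)
  xyz[base_idx, ] <- apply_rot(xyz[base_idx, , drop = FALSE],
                               rot_axis(alpha, axis, pts$ii))
  xyz
}

#' Generate a trajectory with scheduled base flips and thermal jitter
#'
#' Starting from [generate_duplex_frame()], rotates each scheduled residue's
#' nucleobase to an extra-helical pose (flip pseudo-dihedral
#' `sign * out_angle`, sign set by the groove) in its scheduled frames, and
#' adds isotropic Gaussian jitter to all atoms.  Deterministic given `seed`.
#'
#' @param construct an [rna_construct].
#' @param schedules list of [flip_schedule] objects (may be empty).
#' @param jitter_sd per-coordinate Gaussian jitter standard deviation (A).
#' @param nframes number of frames (>= 1).
#' @param seed integer seed; the global RNG state is preserved.
#' @param out_angle magnitude of the extra-helical flip angle (degrees).
#' @param ... passed to [generate_duplex_frame()].
#' @return an [rna_trajectory] with attribute `schedules` containing the
#'   realized per-frame states.
#' @export
generate_flip_trajectory <- function(construct, schedules = list(),
                                     jitter_sd = 0, nframes = 50, seed = 1,
                                     out_angle = 170, ...) {
  stopifnot(nframes >= 1, jitter_sd >= 0)
  base <- generate_duplex_frame(construct, ...)
  xyz0 <- get_frame(base, 1)
  nat <- nrow(xyz0)
  states <- lapply(schedules, schedule_states, nframes = nframes)
  resnos <- vapply(schedules, function(s) resolve_residue(base, s$residue), 0L)
  targets <- vapply(schedules, function(s)
    if (s$groove == "major") -out_angle else out_angle, 0)
  coords <- array(NA_real_, c(nat, 3, nframes))
  with_seed(seed, {
    for (f in seq_len(nframes)) {
      xyz <- xyz0
      for (k in seq_along(schedules)) {
        if (states[[k]][f])
          xyz <- set_flip_angle(xyz, base, resnos[k], targets[k],
                                construct)
      }
      if (jitter_sd > 0)
        xyz <- xyz + matrix(rnorm(nat * 3, sd = jitter_sd), nat, 3)
      coords[, , f] <- xyz
    }
  })
  traj <- rna_trajectory(base$topology, coords)
  traj$construct <- construct
  attr(traj, "schedules") <- Map(function(s, st) {
    s$states <- st
    s
  }, schedules, states)
  traj
}
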