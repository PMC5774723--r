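# Base-flip pseudo-dihedral angle: the four-point torsion over (i) the
# centre of mass of the flipping nucleobase, (ii) the COM of its phosphate
# group, (iii) the COM of the 3'-neighbour's phosphate group and (iv) the
# COM of the nucleobases of the reference pairs flanking the analysed
# nucleotide.  Intra-helical bases sit near 0 degrees; extra-helical bases
# near +-180, with negative angles facing the major groove.

resno_by_strand_pos <- function(traj, strand, pos) {
  tp <- traj$topology
  hit <- unique(tp$resno[tp$strand == strand & tp$pos == pos])
  if (length(hit) != 1L) return(NA_integer_)
  hit
}

com_of <- function(xyz, idx) colMeans(xyz[idx, , drop = FALSE])

base_heavy_idx <- function(traj, resno) {
  tp <- traj$topology
  which(tp$resno == resno &
          mapply(function(rt, at) at %in% BASE_ATOMS[[rt]], tp$restype, tp$elety))
}

phosphate_idx <- function(traj, resno) {
  tp <- traj$topology
  which(tp$resno == resno & tp$elety %in% c("P", "OP1", "OP2"))
}

# the four pseudo-dihedral points for one residue
pseudo_dihedral_points <- function(traj, resno, construct, xyz = NULL,
                                   frame = 1L) {
  if (is.null(xyz)) xyz <- get_frame(traj, frame)
  tp <- traj$topology
  row1 <- tp[tp$resno == resno, ][1, ]
  own_p <- phosphate_idx(traj, resno)
  if (length(own_p) < 3)
    stop("residue ", row1$label, " has no complete phosphate group")
  nxt <- resno_by_strand_pos(traj, row1$strand, row1$pos + 1L)
  if (is.na(nxt))
    stop("residue ", row1$label, " has no 3' neighbour")
  nxt_p <- phosphate_idx(traj, nxt)
  if (length(nxt_p) < 3)
    stop("3' neighbour of ", row1$label, " has no complete phosphate group")
  rp <- construct$reference_pairs
  own_col <- if (row1$strand == "A") 1L else 2L
  ppos <- rp[, own_col]
  before <- ppos[ppos < row1$pos]; after <- ppos[ppos > row1$pos]
  if (length(before) == 0 || length(after) == 0)
    stop("residue ", row1$label, " has no flanking reference pairs")
  flank <- rp[ppos %in% c(max(before), min(after)), , drop = FALSE]
  flank_idx <- unlist(lapply(seq_len(nrow(flank)), function(k) {
    c(base_heavy_idx(traj, resno_by_strand_pos(traj, "A", flank[k, 1])),
      base_heavy_idx(traj, resno_by_strand_pos(traj, "B", flank[k, 2])))
  }))
  list(i = com_of(xyz, base_heavy_idx(traj, resno)),
       ii = com_of(xyz, own_p),
       iii = com_of(xyz, nxt_p),
       iv = com_of(xyz, flank_idx))
}

#' Base-flip pseudo-dihedral angle
#'
#' Computes the four-point flip pseudo-dihedral of a residue for the
#' requested frames.  The residue must have a complete phosphate group, a 3'
#' neighbour with a phosphate, and reference pairs flanking it on both sides
#' in the construct.
#'
#' @param traj an [rna_trajectory].
#' @param residue E. coli residue label or `resno`.
#' @param construct the [rna_construct] supplying the reference pairing;
#'   defaults to the construct attached to generated trajectories.
#' @param frames frame indices (default all).
#' @return numeric vector of angles in degrees, in (-180, 180].
#' @export
pseudo_dihedral <- function(traj, residue, construct = traj$construct,
                            frames = NULL) {
  if (is.null(construct)) stop("no construct available for reference pairing")
  resno <- resolve_residue(traj, residue)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  vapply(frames, function(f) {
    pts <- pseudo_dihedral_points(traj, resno, construct, frame = f)
    dihedral_angle(pts$i, pts$ii, pts$iii, pts$iv)
  }, 0)
}

#' Classify flip angles into intra/extra-helical states
#'
#' States: `"in"` for angles inside `(-in_threshold, in_threshold)`,
#' `"out"` for `|angle| >= out_threshold`, `"intermediate"` otherwise.
#' Negative angles face the major groove, positive the minor groove.
#'
#' @param angles numeric vector of flip angles (degrees).
#' @param in_threshold,out_threshold state thresholds (degrees).
#' @return data frame (`frame`, `angle`, `state`, `groove`) with summary
#'   fractions in attribute `"fractions"`.
#' @export
classify_flip <- function(angles, in_threshold = 50, out_threshold = 140) {
  state <- ifelse(abs(angles) >= out_threshold, "out",
                  ifelse(abs(angles) < in_threshold, "in", "intermediate"))
  groove <- ifelse(angles < 0, "major", ifelse(angles > 0, "minor", "n/a"))
  out <- data.frame(frame = seq_along(angles), angle = angles,
                    state = state, groove = groove,
                    stringsAsFactors = FALSE)
  frac <- c(`in` = mean(state == "in"),
            intermediate = mean(state == "intermediate"),
            out = mean(state == "out"))
  attr(out, "fractions") <- frac
  out
}

#' Long-format flip-angle report for several residues
#'
#' @param traj an [rna_trajectory].
#' @param residues character vector of residue labels.
#' @param construct reference pairing (defaults to the attached construct).
#' @param in_threshold,out_threshold passed to [classify_flip()].
#' @return data frame with columns `frame`, `residue`, `angle_deg`, `state`,
#'   `groove` (one row per frame and residue).
#' @export
flip_timeseries_report <- function(traj, residues,
                                   construct = traj$construct,
                                   in_threshold = 50, out_threshold = 140) {
  do.call(rbind, lapply(residues, function(rl) {
    ang <- pseudo_dihedral(traj, rl, construct)
    cl <- classify_flip(ang, in_threshold, out_threshold)
    data.frame(frame = cl$frame, residue = rl, angle_deg = cl$angle,
               state = cl$state, groove = cl$groove,
               stringsAsFactors = FALSE)
  }))
}
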