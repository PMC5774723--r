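# Hydrogen-bond detection (donor-acceptor distance <= 3.5 A and
# acceptor-hydrogen-donor angle >= 150 deg) and base-pair classification by
# hydrogen-bonding edge (Watson-Crick / Hoogsteen / sugar), including the
# corner-atom asterisk convention for single-bond pairs whose edge cannot be
# assigned uniquely.

EDGE_PRIORITY <- c("WC", "HG", "Sugar")

#' Detect hydrogen bonds in a trajectory frame
#'
#' All donor-H...acceptor triples between different residues satisfying both
#' geometric criteria.  Donors are the standard nucleobase amine/imine
#' nitrogens plus the ribose O2'; acceptors are the base carbonyl oxygens and
#' ring nitrogens plus (optionally) the backbone oxygens.  Donors whose
#' hydrogen is missing from the topology are skipped with a warning (see
#' [place_hydrogens()]).
#'
#' @param traj an [rna_trajectory].
#' @param frame frame index.
#' @param max_dist maximal donor-acceptor distance (Angstrom).
#' @param min_angle minimal acceptor-hydrogen-donor angle (degrees).
#' @param backbone_acceptors include backbone/sugar oxygens as acceptors.
#' @return data frame: `don_resno`, `don_label`, `don_atom`, `h_atom`,
#'   `acc_resno`, `acc_label`, `acc_atom`, `distance`, `angle`.
#' @export
detect_hbonds <- function(traj, frame = 1L, max_dist = 3.5, min_angle = 150,
                          backbone_acceptors = TRUE) {
  xyz <- get_frame(traj, frame)
  tp <- traj$topology
  don <- NULL
  acc <- NULL
  skipped <- character()
  for (rn in unique(tp$resno)) {
    rows <- tp[tp$resno == rn, ]
    rt <- rows$restype[1]
    if (!rt %in% names(BASE_DONORS)) next
    for (d in c(BASE_DONORS[[rt]], "O2'")) {
      di <- rows$eleno[rows$elety == d]
      if (length(di) == 0) next
      hs <- DONOR_HYDROGENS[[d]]
      hi <- rows$eleno[rows$elety %in% hs]
      if (length(hi) == 0) {
        skipped <- c(skipped, paste0(rows$label[1], ":", d))
        next
      }
      don <- rbind(don, data.frame(resno = rn, label = rows$label[1],
                                   atom = d, di = di, hi = hi))
    }
    accs <- BASE_ACCEPTORS[[rt]]
    if (backbone_acceptors) accs <- c(accs, BACKBONE_ACCEPTORS)
    ai <- rows$eleno[rows$elety %in% accs]
    if (length(ai))
      acc <- rbind(acc, data.frame(resno = rn, label = rows$label[1],
                                   atom = rows$elety[match(ai, rows$eleno)],
                                   ai = ai))
  }
  if (length(skipped))
    warning(length(skipped), " donor(s) without hydrogens skipped (",
            paste(head(skipped, 3), collapse = ", "),
            if (length(skipped) > 3) ", ..." else "",
            "); see place_hydrogens()", call. = FALSE)
  empty <- data.frame(don_resno = integer(), don_label = character(),
                      don_atom = character(), h_atom = character(),
                      acc_resno = integer(), acc_label = character(),
                      acc_atom = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  if (is.null(don) || is.null(acc)) return(empty)
  D <- xyz[don$di, , drop = FALSE]
  A <- xyz[acc$ai, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rep(1, nrow(A))) +
    outer(rep(1, nrow(D)), rowSums(A^2)) - 2 * D %*% t(A)
  cand <- which(d2 <= max_dist^2 + 1e-12 &
                  outer(don$resno, acc$resno, "!="), arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  out <- lapply(seq_len(nrow(cand)), function(k) {
    dd <- cand[k, 1]; aa <- cand[k, 2]
    ang <- angle_at(xyz[acc$ai[aa], ], xyz[don$hi[dd], ], xyz[don$di[dd], ])
    if (ang < min_angle) return(NULL)
    data.frame(don_resno = don$resno[dd], don_label = don$label[dd],
               don_atom = don$atom[dd],
               h_atom = tp$elety[don$hi[dd]],
               acc_resno = acc$resno[aa], acc_label = acc$label[aa],
               acc_atom = acc$atom[aa],
               distance = sqrt(max(0, d2[dd, aa])), angle = ang,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

# bonds usable for base-pair classification: both end atoms on a base edge
# (or the ribose O2'); purely backbone-mediated contacts are excluded
classifiable_bonds <- function(hb, tp, edge_table) {
  if (nrow(hb) == 0) return(hb)
  restype_of <- function(rn) tp$restype[match(rn, tp$resno)]
  ok <- vapply(seq_len(nrow(hb)), function(k) {
    md <- edge_membership(restype_of(hb$don_resno[k]), hb$don_atom[k], edge_table)
    ma <- edge_membership(restype_of(hb$acc_resno[k]), hb$acc_atom[k], edge_table)
    length(md) > 0 && length(ma) > 0 &&
      !(hb$don_atom[k] %in% BACKBONE_ACCEPTORS[-1]) &&
      !(hb$acc_atom[k] %in% BACKBONE_ACCEPTORS[-1])
  }, logical(1))
  hb[ok, , drop = FALSE]
}

resolve_edge <- function(memberships) {
  if (length(memberships) == 1 && length(memberships[[1]]) == 2) {
    m <- memberships[[1]][order(match(memberships[[1]], EDGE_PRIORITY))]
    return(paste(m, collapse = "*"))
  }
  inter <- Reduce(intersect, memberships)
  if (length(inter) == 1) return(inter)
  if (length(inter) > 1) return(inter[which.min(match(inter, EDGE_PRIORITY))])
  votes <- table(unlist(memberships))
  top <- names(votes)[votes == max(votes)]
  top[which.min(match(top, EDGE_PRIORITY))]
}

#' Classify the base pair formed by two residues
#'
#' Maps every base-mediated hydrogen bond between residues `i` and `j` to
#' the hydrogen-bonding edges of the participating atoms and assigns each
#' residue the unique edge consistent with its bonded atoms.  If the pair is
#' held by a single hydrogen bond through an atom at the corner of two edges
#' the ambiguous type `Edge1*Edge2` is reported for that residue.
#'
#' @param traj an [rna_trajectory].
#' @param i,j residue labels or `resno` indices (`i != j`).
#' @param frame frame index.
#' @param edge_table atom-to-edge table, see [default_edge_table()].
#' @param hbonds optional precomputed [detect_hbonds()] table for the frame.
#' @return a list of class `base_pair_record` with `res_i`, `res_j`,
#'   `label_i`, `label_j`, `edge_i`, `edge_j`, `type` (e.g. `"WC/WC"`),
#'   `hbonds`, `is_wcwc`; or `NULL` when no base-mediated bond links the
#'   residues.
#' @export
classify_base_pair <- function(traj, i, j, frame = 1L,
                               edge_table = default_edge_table(),
                               hbonds = NULL) {
  ri <- resolve_residue(traj, i); rj <- resolve_residue(traj, j)
  if (ri == rj) stop("i and j must differ")
  if (is.null(hbonds)) hbonds <- detect_hbonds(traj, frame)
  tp <- traj$topology
  hb <- hbonds[(hbonds$don_resno == ri & hbonds$acc_resno == rj) |
                 (hbonds$don_resno == rj & hbonds$acc_resno == ri), ,
               drop = FALSE]
  hb <- classifiable_bonds(hb, tp, edge_table)
  if (nrow(hb) == 0) return(NULL)
  side_atoms <- function(rn) {
    ifelse(hb$don_resno == rn, hb$don_atom, hb$acc_atom)
  }
  restype_of <- function(rn) tp$restype[match(rn, tp$resno)]
  mem_i <- lapply(side_atoms(ri), edge_membership, restype = restype_of(ri),
                  edge_table = edge_table)
  mem_j <- lapply(side_atoms(rj), edge_membership, restype = restype_of(rj),
                  edge_table = edge_table)
  edge_i <- resolve_edge(mem_i)
  edge_j <- resolve_edge(mem_j)
  structure(list(
    res_i = ri, res_j = rj,
    label_i = tp$label[match(ri, tp$resno)],
    label_j = tp$label[match(rj, tp$resno)],
    edge_i = edge_i, edge_j = edge_j,
    type = paste(edge_i, edge_j, sep = "/"),
    hbonds = hb,
    is_wcwc = identical(edge_i, "WC") && identical(edge_j, "WC")),
    class = "base_pair_record")
}

#' @export
print.base_pair_record <- function(x, ...) {
  cat("<base_pair_record> ", x$label_i, ":", x$label_j, "  ", x$type,
      "  (", nrow(x$hbonds), " H-bonds)\n", sep = "")
  invisible(x)
}

# all classified base pairs of one frame as a data frame
classify_frame_pairs <- function(traj, frame = 1L,
                                 edge_table = default_edge_table(),
                                 hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(traj, frame)
  tp <- traj$topology
  hb <- classifiable_bonds(hbonds, tp, edge_table)
  empty <- data.frame(res_i = integer(), res_j = integer(),
                      label_i = character(), label_j = character(),
                      edge_i = character(), edge_j = character(),
                      type = character(), n_hbonds = integer(),
                      is_wcwc = logical(), stringsAsFactors = FALSE)
  if (nrow(hb) == 0) return(empty)
  lo <- pmin(hb$don_resno, hb$acc_resno)
  hi <- pmax(hb$don_resno, hb$acc_resno)
  keys <- unique(paste(lo, hi))
  out <- lapply(keys, function(k) {
    rn <- as.integer(strsplit(k, " ")[[1]])
    rec <- classify_base_pair(traj, rn[1], rn[2], frame, edge_table, hbonds)
    if (is.null(rec)) return(NULL)
    data.frame(res_i = rec$res_i, res_j = rec$res_j,
               label_i = rec$label_i, label_j = rec$label_j,
               edge_i = rec$edge_i, edge_j = rec$edge_j, type = rec$type,
               n_hbonds = nrow(rec$hbonds), is_wcwc = rec$is_wcwc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Count hydrogen bonds in WC-WC and non-WC-WC pairs
#'
#' A WC-WC pair is one in which both residues interact through their
#' Watson-Crick edges (not necessarily a canonical A:U / G:C pair).  Each
#' classified pair contributes its hydrogen bonds to exactly one counter.
#'
#' @param traj an [rna_trajectory].
#' @param frame frame index.
#' @param edge_table atom-to-edge table.
#' @return integer count.
#' @export
count_wcwc_hbonds <- function(traj, frame = 1L,
                              edge_table = default_edge_table()) {
  pairs <- classify_frame_pairs(traj, frame, edge_table)
  sum(pairs$n_hbonds[pairs$is_wcwc])
}

#' @rdname count_wcwc_hbonds
#' @export
count_nonwcwc_hbonds <- function(traj, frame = 1L,
                                 edge_table = default_edge_table()) {
  pairs <- classify_frame_pairs(traj, frame, edge_table)
  sum(pairs$n_hbonds[!pairs$is_wcwc])
}

#' Windowed WC-WC / non-WC-WC hydrogen-bond counts
#'
#' @param traj an [rna_trajectory].
#' @param window frames per averaging window.
#' @param edge_table atom-to-edge table.
#' @return data frame `window`, `frame_from`, `frame_to`, `wcwc`, `nonwcwc`
#'   (window means).
#' @export
hbond_count_timeseries <- function(traj, window = 1L,
                                   edge_table = default_edge_table()) {
  nf <- n_frames(traj)
  wc <- numeric(nf); nwc <- numeric(nf)
  for (f in seq_len(nf)) {
    pairs <- classify_frame_pairs(traj, f, edge_table)
    wc[f] <- sum(pairs$n_hbonds[pairs$is_wcwc])
    nwc[f] <- sum(pairs$n_hbonds[!pairs$is_wcwc])
  }
  idx <- split(seq_len(nf), ceiling(seq_len(nf) / window))
  data.frame(window = seq_along(idx),
             frame_from = vapply(idx, min, 0L),
             frame_to = vapply(idx, max, 0L),
             wcwc = vapply(idx, function(ii) mean(wc[ii]), 0),
             nonwcwc = vapply(idx, function(ii) mean(nwc[ii]), 0))
}

#' Base-pair occupancy table over a trajectory
#'
#' Fraction of frames in which each (residue pair, edge type) classification
#' holds.  Entries at or below `threshold` are suppressed from the report but
#' retained in the full table.
#'
#' @param traj an [rna_trajectory].
#' @param threshold minimum reported fraction (strictly greater than).
#' @param frames frame indices (default all).
#' @param edge_table atom-to-edge table.
#' @return object of class `occupancy_table`: list with `table` (all
#'   entries), `report` (entries above threshold), `n_frames`, `threshold`.
#' @export
pair_occupancy <- function(traj, threshold = 0.05, frames = NULL,
                           edge_table = default_edge_table()) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  counts <- list()
  for (f in frames) {
    pairs <- classify_frame_pairs(traj, f, edge_table)
    if (nrow(pairs) == 0) next
    key <- paste(pairs$label_i, pairs$label_j, pairs$type, sep = "|")
    for (k in seq_along(key)) {
      if (is.null(counts[[key[k]]]))
        counts[[key[k]]] <- c(pairs[k, c("label_i", "label_j", "type")], n = 0)
      counts[[key[k]]]$n <- counts[[key[k]]]$n + 1
    }
  }
  tab <- do.call(rbind, lapply(counts, function(e)
    data.frame(pair_i = e$label_i, pair_j = e$label_j, type = e$type,
               fraction = e$n / length(frames), stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(pair_i = character(), pair_j = character(),
                      type = character(), fraction = numeric())
  rownames(tab) <- NULL
  tab <- tab[order(tab$pair_i, tab$pair_j, -tab$fraction), , drop = FALSE]
  structure(list(table = tab, report = tab[tab$fraction > threshold, ,
                                           drop = FALSE],
                 n_frames = length(frames), threshold = threshold),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("<occupancy_table> ", nrow(x$table), " pair types over ", x$n_frames,
      " frames; ", nrow(x$report), " above ",
      100 * x$threshold, "%\n", sep = "")
  if (nrow(x$report)) print(x$report, row.names = FALSE)
  invisible(x)
}

#' Construct missing polar hydrogens at idealized positions
#'
#' Adds idealized polar hydrogens for nucleobase donors (amine hydrogens in
#' the base plane at +-60 degrees off the exocyclic bond extension, imine
#' hydrogens along the outward ring radial) and the ribose O2' (along the
#' C2'-O2' extension) wherever the topology lacks them.
#'
#' @param traj an [rna_trajectory].
#' @return a new [rna_trajectory] including the constructed hydrogens.
#' @export
place_hydrogens <- function(traj) {
  tp <- traj$topology
  nf <- n_frames(traj)
  add_tp <- NULL
  add_xyz <- vector("list", nf)
  for (rn in unique(tp$resno)) {
    rows <- tp[tp$resno == rn, ]
    rt <- rows$restype[1]
    if (!rt %in% names(BASE_DONORS)) next
    ring <- rows$eleno[rows$elety %in% RING6_ATOMS]
    donors <- c(BASE_DONORS[[rt]], "O2'")
    for (d in donors) {
      di <- rows$eleno[rows$elety == d]
      if (length(di) == 0) next
      hs <- DONOR_HYDROGENS[[d]]
      missing_h <- setdiff(hs, rows$elety)
      if (length(missing_h) == 0) next
      anchor <- switch(d, N6 = "C6", N4 = "C4", N2 = "C2", "O2'" = "C2'",
                       NULL)
      ai <- if (!is.null(anchor)) rows$eleno[rows$elety == anchor] else integer()
      for (f in seq_len(nf)) {
        xyz <- get_frame(traj, f)
        dpos <- xyz[di, ]
        if (length(ai) == 1) {
          u <- vunit(dpos - xyz[ai, ])
        } else {
          u <- vunit(dpos - colMeans(xyz[ring, , drop = FALSE]))
        }
        if (length(missing_h) == 1) {
          hpos <- rbind(dpos + 1.0 * u)
        } else {
          nrm <- vunit(vcross(xyz[ring[2], ] - xyz[ring[1], ],
                              xyz[ring[3], ] - xyz[ring[1], ]))
          r60 <- function(s) {
            rot <- rot_axis(s * 60, nrm, c(0, 0, 0))
            dpos + 1.0 * as.vector(rot$R %*% u)
          }
          hpos <- rbind(r60(1), r60(-1))
        }
        add_xyz[[f]] <- rbind(add_xyz[[f]], hpos[seq_along(missing_h), ,
                                                 drop = FALSE])
      }
      add_tp <- rbind(add_tp, data.frame(
        eleno = NA_integer_, elety = missing_h, restype = rt, resno = rn,
        strand = rows$strand[1], pos = rows$pos[1], label = rows$label[1],
        element = "H", stringsAsFactors = FALSE))
    }
  }
  if (is.null(add_tp)) return(traj)
  tp2 <- rbind(tp, add_tp)
  tp2$eleno <- seq_len(nrow(tp2))
  coords <- array(NA_real_, c(nrow(tp2), 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- rbind(get_frame(traj, f), add_xyz[[f]])
  out <- rna_trajectory(tp2, coords, traj$frame_interval)
  out$construct <- traj$construct
  out
}
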