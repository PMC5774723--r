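# Trajectory container and multi-model PDB I/O.  Coordinates are stored as a
# natoms x 3 x nframes array in Angstrom; the topology is a plain data frame
# so selections compose with ordinary subsetting.

#' Trajectory container
#'
#' @param topology data frame with one row per atom: columns `eleno`,
#'   `elety` (atom name), `restype` (A/C/G/U), `resno` (1-based residue
#'   index over the whole system), `strand` (chain id), `pos` (position
#'   within its strand), `label` (E. coli residue label or `"ext..."`),
#'   `element`.
#' @param coords numeric array `natoms x 3 x nframes` (Angstrom).
#' @param frame_interval optional time between frames (arbitrary units).
#' @return object of class `rna_trajectory`.
#' @export
rna_trajectory <- function(topology, coords, frame_interval = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(nrow(topology) == dim(coords)[1], dim(coords)[2] == 3)
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "rna_trajectory")
}

#' @export
print.rna_trajectory <- function(x, ...) {
  cat("<rna_trajectory> ", dim(x$coords)[1], " atoms, ",
      length(unique(x$topology$resno)), " residues, ",
      n_frames(x), " frames\n", sep = "")
  invisible(x)
}

#' @rdname rna_trajectory
#' @param traj an `rna_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#'
#' @param traj an [rna_trajectory].
#' @param frame 1-based frame index.
#' @return `natoms x 3` matrix with atom names as rownames.
#' @export
get_frame <- function(traj, frame = 1L) {
  if (frame < 1 || frame > n_frames(traj)) stop("frame index out of range")
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  rownames(m) <- traj$topology$elety
  m
}

#' Atom selection helper
#'
#' @param traj an [rna_trajectory].
#' @param residues optional residue labels (e.g. `"A1493"`) or `resno`
#'   indices.
#' @param strand optional strand id.
#' @param heavy if `TRUE` keep only non-hydrogen atoms.
#' @param base_only if `TRUE` keep only nucleobase atoms.
#' @param exclude_ext if `TRUE` drop terminal-extension residues.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(traj, residues = NULL, strand = NULL, heavy = TRUE,
                         base_only = FALSE, exclude_ext = FALSE) {
  tp <- traj$topology
  keep <- rep(TRUE, nrow(tp))
  if (!is.null(residues)) {
    keep <- keep & if (is.numeric(residues)) tp$resno %in% residues
                   else tp$label %in% residues
  }
  if (!is.null(strand)) keep <- keep & tp$strand %in% strand
  if (heavy) keep <- keep & tp$element != "H"
  if (base_only) {
    isbase <- mapply(function(rt, at) at %in% BASE_ATOMS[[rt]],
                     tp$restype, tp$elety)
    keep <- keep & isbase
  }
  if (exclude_ext) keep <- keep & !grepl("^ext", tp$label)
  which(keep)
}

residue_atoms <- function(traj, resno, base_only = FALSE, heavy = TRUE) {
  select_atoms(traj, residues = resno, heavy = heavy, base_only = base_only)
}

# resno of a residue given by E. coli label or resno
resolve_residue <- function(traj, residue) {
  tp <- traj$topology
  if (is.numeric(residue)) {
    if (!residue %in% tp$resno) stop("unknown residue index: ", residue)
    return(as.integer(residue))
  }
  hit <- unique(tp$resno[tp$label == residue])
  if (length(hit) != 1L) stop("unknown or ambiguous residue label: ", residue)
  hit
}

#' Read a multi-model PDB trajectory
#'
#' Thin wrapper around [bio3d::read.pdb()]: atoms keep file order, frames
#' follow MODEL order, elements are inferred from atom names when absent.
#' Residue metadata (strand/pos/label) is reconstructed from chain ids and
#' an optional construct.
#'
#' @param path PDB file path.
#' @param construct optional [rna_construct] used to attach E. coli labels.
#' @return an [rna_trajectory].
#' @export
read_trajectory <- function(path, construct = NULL) {
  # validate MODEL blocks before parsing: all models must have the same
  # number of coordinate records
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM|HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) != 1)
      stop("inconsistent atom counts between models in ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nat <- nrow(at)
  nfr <- nrow(pdb$xyz)
  coords <- array(NA_real_, c(nat, 3, nfr))
  for (f in seq_len(nfr))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 trimws(at$elesy), element_of(at$elety))
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  key <- paste(chain, at$resno)
  resno <- match(key, unique(key))
  pos <- stats::ave(resno, chain, FUN = function(v) match(v, unique(v)))
  label <- paste0("ext", resno)
  if (!is.null(construct)) {
    strands <- list(A = construct$strandA, B = construct$strandB)
    for (ch in names(strands)) {
      idx <- chain == ch
      if (!any(idx)) next
      lab <- strands[[ch]]$numbering[pos[idx]]
      lab[lab == "ext"] <- paste0("ext_", ch, pos[idx][lab == "ext"])
      label[idx] <- lab
    }
  }
  topology <- data.frame(
    eleno = seq_len(nat), elety = at$elety, restype = trimws(at$resid),
    resno = resno, strand = chain, pos = pos, label = label,
    element = elem, stringsAsFactors = FALSE)
  rna_trajectory(topology, coords)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an [rna_trajectory].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  tp <- traj$topology
  nfr <- n_frames(traj)
  xyz <- t(vapply(seq_len(nfr),
                  function(f) as.numeric(t(get_frame(traj, f))),
                  numeric(3 * nrow(tp))))
  if (nfr == 1L) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz, resno = tp$pos, chain = tp$strand,
                   resid = tp$restype, elety = tp$elety)
  invisible(path)
}
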