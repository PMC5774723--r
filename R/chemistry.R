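# Chemical knowledge tables: ring/base atom sets, hydrogen-bond donors and
# acceptors, and the per-base atom-to-edge maps used for base-pair
# classification.  The edge and corner assignments follow the
# Leontis-Westhof edge nomenclature and can be overridden per call.

GLYCO_ATOM <- c(A = "N9", G = "N9", C = "N1", U = "N1")

RING6_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6")

BASE_ATOMS <- list(
  A = c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8", "N9"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6", "O6", "N2", "N7", "C8", "N9"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"))

BASE_HYDROGENS <- list(
  A = c("H61", "H62"), G = c("H1", "H21", "H22"),
  C = c("H41", "H42"), U = "H3")

# heavy atom each polar hydrogen rides on
DONOR_HYDROGENS <- list(
  N6 = c("H61", "H62"), N4 = c("H41", "H42"), N2 = c("H21", "H22"),
  N1 = "H1", N3 = "H3", "O2'" = "HO2'")

BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", U = "N3")

BASE_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
  C = c("N3", "O2"), U = c("O2", "O4"))

BACKBONE_ACCEPTORS <- c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2")

#' Default atom-to-edge table for base-pair classification
#'
#' For each base the hydrogen-bonding heavy atoms are assigned to the
#' Watson-Crick (WC), Hoogsteen (HG) or sugar edge.  Atoms sitting at the
#' corner between two edges belong to both; a pair interacting through a
#' single hydrogen bond on such an atom cannot be assigned a unique edge and
#' is reported with the ambiguous `Edge1*Edge2` type.  The ribose O2' always
#' maps to the sugar edge.
#'
#' @return named list: for each base, a list of character vectors `WC`, `HG`,
#'   `Sugar`.
#' @export
default_edge_table <- function() {
  list(
    A = list(WC = c("N1", "C2", "N6"), HG = c("N7", "N6"), Sugar = "N3"),
    G = list(WC = c("N1", "N2", "O6"), HG = c("N7", "O6"), Sugar = c("N3", "N2")),
    C = list(WC = c("N3", "O2", "N4"), HG = c("N4", "C5"), Sugar = "O2"),
    U = list(WC = c("N3", "O2", "O4"), HG = c("O4", "C5"), Sugar = "O2"))
}

edge_membership <- function(restype, atom, edge_table = default_edge_table()) {
  if (atom == "O2'") return("Sugar")
  et <- edge_table[[restype]]
  names(et)[vapply(et, function(v) atom %in% v, logical(1))]
}

element_of <- function(atom_name) {
  substr(gsub("^[0-9]+", "", atom_name), 1, 1)
}

# --- idealized A-form templates --------------------------------------------

.template_env <- new.env(parent = emptyenv())

#' Idealized A-form nucleotide pair templates
#'
#' Loads the idealized rigid-nucleotide coordinate templates shipped with the
#' package (planar idealized bases with polar hydrogens plus a schematic
#' sugar-phosphate backbone, arranged as canonical pairs in a common pair
#' frame with the helix axis along z).  Pair types `GC`, `CG`, `AU`, `UA` are
#' the canonical Watson-Crick pairs; `AUHG` is a Hoogsteen-paired A:U used to
#' build non-canonical fixtures.
#'
#' @param pair pair type, one of `"GC"`, `"CG"`, `"AU"`, `"UA"`, `"AUHG"`,
#'   or `NULL` for the full table.
#' @return data frame with columns `pair`, `role` (X = first-named strand
#'   side), `restype`, `atom`, `x`, `y`, `z`.
#' @export
aform_templates <- function(pair = NULL) {
  if (is.null(.template_env$tpl)) {
    path <- system.file("extdata", "aform_templates.csv",
                        package = "asitetools", mustWork = TRUE)
    .template_env$tpl <- read.csv(path, stringsAsFactors = FALSE)
  }
  tpl <- .template_env$tpl
  if (is.null(pair)) return(tpl)
  out <- tpl[tpl$pair == pair, ]
  if (nrow(out) == 0) stop("unknown template pair type: ", pair)
  out
}

# coordinates of one template nucleotide as a named matrix
template_nucleotide <- function(pair, role) {
  tpl <- aform_templates(pair)
  tpl <- tpl[tpl$role == role, ]
  m <- as.matrix(tpl[, c("x", "y", "z")])
  rownames(m) <- tpl$atom
  m
}
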