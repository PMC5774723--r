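# Domain model for the A-site constructs: RNA strands with E. coli
# numbering, bipartite duplex constructs with declared reference pairings,
# and the antiparallel mismatch scan used to compare the 2'-O-Me oligomers
# against the prokaryotic and eukaryotic targets.

RNA_ALPHABET <- c("A", "C", "G", "U")
WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

#' RNA strand with per-position numbering
#'
#' An `rna_strand` holds a 5'-to-3' sequence over `{A,C,G,U}`, its chemistry
#' (unmodified RNA or 2'-O-methylated RNA), and a per-position numbering map
#' that either carries an E. coli ribosome residue label (e.g. `"A1493"`) or
#' `"ext"` for positions belonging to the stabilizing terminal extensions.
#'
#' @param id short strand label.
#' @param sequence character scalar, 5' to 3', letters in `{A,C,G,U}`.
#' @param chemistry `"RNA"` or `"2OMe-RNA"`.
#' @param numbering character vector of length `nchar(sequence)` of E. coli
#'   labels or `"ext"`; defaults to all-`"ext"`.
#' @return object of class `rna_strand`.
#' @export
rna_strand <- function(id, sequence, chemistry = c("RNA", "2OMe-RNA"),
                       numbering = NULL) {
  chemistry <- match.arg(chemistry)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters <- strsplit(sequence, "")[[1]]
  if (!all(letters %in% RNA_ALPHABET))
    stop("sequence of '", id, "' contains letters outside {A,C,G,U}")
  if (is.null(numbering)) numbering <- rep("ext", length(letters))
  if (length(numbering) != length(letters))
    stop("numbering must cover every position exactly once")
  structure(list(id = id, sequence = sequence, chemistry = chemistry,
                 numbering = numbering),
            class = "rna_strand")
}

#' @export
print.rna_strand <- function(x, ...) {
  cat("<rna_strand> ", x$id, " (", x$chemistry, ", ",
      nchar(x$sequence), " nt)\n  5'-", x$sequence, "-3'\n", sep = "")
  invisible(x)
}

#' @export
length.rna_strand <- function(x) nchar(x$sequence)

strand_letters <- function(strand) strsplit(strand$sequence, "")[[1]]

#' Bipartite duplex construct
#'
#' Couples strands A and B of an A-site model with the declared reference
#' Watson-Crick pairing.  Every reference pair must be sequence-complementary
#' (A:U or G:C); non-canonical interactions (e.g. U1406:U1495) are observed
#' by the analysis modules, not declared here.
#'
#' @param strandA,strandB [rna_strand] objects.
#' @param reference_pairs two-column matrix or data frame of (posA, posB)
#'   1-based positions.
#' @param label `"prokaryotic"` or `"eukaryotic"` (free labels allowed for
#'   user fixtures).
#' @return object of class `rna_construct`.
#' @export
rna_construct <- function(strandA, strandB, reference_pairs, label = "custom") {
  stopifnot(inherits(strandA, "rna_strand"), inherits(strandB, "rna_strand"))
  rp <- as.matrix(reference_pairs)
  storage.mode(rp) <- "integer"
  colnames(rp) <- c("posA", "posB")
  la <- strand_letters(strandA); lb <- strand_letters(strandB)
  if (any(rp[, 1] < 1 | rp[, 1] > length(la) | rp[, 2] < 1 | rp[, 2] > length(lb)))
    stop("reference pair position out of range")
  ok <- WC_PARTNER[la[rp[, 1]]] == lb[rp[, 2]]
  if (!all(ok))
    stop("reference pairs not sequence-complementary: ",
         paste(which(!ok), collapse = ", "))
  structure(list(strandA = strandA, strandB = strandB,
                 reference_pairs = rp, label = label),
            class = "rna_construct")
}

#' @export
print.rna_construct <- function(x, ...) {
  cat("<rna_construct> ", x$label, ": ", x$strandA$id, " + ", x$strandB$id,
      ", ", nrow(x$reference_pairs), " reference pairs\n", sep = "")
  invisible(x)
}

# numbering for the 23-nt B strands: 4-nt 5' extension, G1488, residues
# 1489-1501, 5-nt 3' extension (3'-terminal dangling C included)
.numbering_B <- function(letters) {
  lab <- rep("ext", 23)
  lab[5:18] <- paste0(letters[5:18], 1488:1501)
  lab
}

# numbering for the 21-nt A strands: 4-nt 5' extension, residues 1401-1412,
# 5-nt 3' extension (3'-terminal dangling G included)
.numbering_A <- function(letters) {
  lab <- rep("ext", 21)
  lab[5:16] <- paste0(letters[5:16], 1401:1412)
  lab
}

# reference pairings shared by both constructs: four stabilizing terminal
# pairs at each end plus the canonical pairs of the 1401-1412/1488-1501 span
.reference_pairs <- function(strandA, strandB) {
  cand <- rbind(
    cbind(1:4, 22:19),          # 5'(A)/3'(B) terminal extension pairs
    cbind(5, 18),               # G1401:C1501
    cbind(8, 14), cbind(9, 13), # C1404:G1497, G1405:C1496
    cbind(11, 11),              # C1407:G1494
    cbind(13, 8),               # C1409:G1491 (prokaryotic only)
    cbind(14, 7), cbind(15, 6), # 1410:1490, 1411:1489
    cbind(16, 5),               # C1412:G1488
    cbind(17:20, 4:1))          # 3'(A)/5'(B) terminal extension pairs
  la <- strand_letters(strandA); lb <- strand_letters(strandB)
  cand[WC_PARTNER[la[cand[, 1]]] == lb[cand[, 2]], , drop = FALSE]
}

#' Registry of the A-site model strands, oligomers and constructs
#'
#' Builds the full registry of study sequences: strands A and B of the
#' prokaryotic and eukaryotic decoding-site models (21 and 23 nt), the three
#' 2'-O-methylated decamers 1489, 1490 and 1491, and the two bipartite
#' constructs with their reference Watson-Crick pairings.  E. coli numbering
#' covers the 1401-1412 span of strand A and 1488-1501 of strand B; the four
#' stabilizing terminal pairs and the two dangling 3' nucleotides are
#' labelled `"ext"`.
#'
#' @return named list of class `asite_registry` with elements `prok_A`,
#'   `prok_B`, `euk_A`, `euk_B`, `oligo_1489`, `oligo_1490`, `oligo_1491`
#'   ([rna_strand]) and `prokaryotic`, `eukaryotic` ([rna_construct]).
#' @export
build_registry <- function() {
  seqs <- c(
    prok_A = "CCGCGCCCGUCACACCACCCG",
    prok_B = "GGGUGGUGAAGUCGUAACGCGGC",
    euk_A  = "CCGCGCCCGUCGCUACACCCG",
    euk_B  = "GGGUGUAAAAGUCGUAACGCGGC")
  reg <- list()
  for (nm in names(seqs)) {
    letters <- strsplit(seqs[[nm]], "")[[1]]
    numbering <- if (grepl("_A$", nm)) .numbering_A(letters) else .numbering_B(letters)
    reg[[nm]] <- rna_strand(nm, seqs[[nm]], "RNA", numbering)
  }
  oligos <- c(oligo_1489 = "ACGACUUCAC",
              oligo_1490 = "UACGACUUCA",
              oligo_1491 = "UUACGACUUC")
  for (nm in names(oligos))
    reg[[nm]] <- rna_strand(nm, oligos[[nm]], "2OMe-RNA")
  reg$prokaryotic <- rna_construct(
    reg$prok_A, reg$prok_B, .reference_pairs(reg$prok_A, reg$prok_B),
    label = "prokaryotic")
  reg$eukaryotic <- rna_construct(
    reg$euk_A, reg$euk_B, .reference_pairs(reg$euk_A, reg$euk_B),
    label = "eukaryotic")
  class(reg) <- "asite_registry"
  reg
}

#' E. coli residue label at a strand position
#'
#' @param strand an [rna_strand].
#' @param position 1-based position.
#' @return the E. coli residue label (e.g. `"A1493"`) or `"ext"`.
#' @export
ecoli_label <- function(strand, position) {
  stopifnot(inherits(strand, "rna_strand"))
  n <- nchar(strand$sequence)
  if (length(position) != 1L || position < 1 || position > n)
    stop("position ", position, " out of range 1..", n, " for ", strand$id)
  strand$numbering[[position]]
}

#' Antiparallel mismatch scan of an oligomer against a target strand
#'
#' Slides the oligomer over every contiguous window of the target and counts
#' antiparallel Watson-Crick mismatches: oligomer position k (5'-3') faces
#' target window position L-k+1, and only A:U and G:C count as matches (G:U
#' wobbles are mismatches).  The best window is the one with the fewest
#' mismatches; ties are broken by the smallest window start.
#'
#' @param oligomer,target [rna_strand] objects; the oligomer must not be
#'   longer than the target.
#' @return object of class `mismatch_report`: list with `oligomer_id`,
#'   `target_id`, `window_start`, `mismatch_count` and logical `match_flags`
#'   (index = oligomer position).
#' @export
count_mismatches <- function(oligomer, target) {
  stopifnot(inherits(oligomer, "rna_strand"), inherits(target, "rna_strand"))
  lo <- strand_letters(oligomer); lt <- strand_letters(target)
  L <- length(lo)
  if (L > length(lt))
    stop("oligomer ", oligomer$id, " is longer than target ", target$id)
  best <- NULL
  for (w in seq_len(length(lt) - L + 1)) {
    # oligomer position k pairs with target position w + L - k
    flags <- WC_PARTNER[lo] == lt[w + L - seq_len(L)]
    mm <- sum(!flags)
    if (is.null(best) || mm < best$mismatch_count) {
      best <- list(oligomer_id = oligomer$id, target_id = target$id,
                   window_start = w, mismatch_count = mm,
                   match_flags = unname(flags))
    }
  }
  structure(best, class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat("<mismatch_report> ", x$oligomer_id, " vs ", x$target_id,
      ": ", x$mismatch_count, " mismatch(es), best window start ",
      x$window_start, "\n", sep = "")
  invisible(x)
}

reverse_complement <- function(sequence) {
  paste(rev(WC_PARTNER[strsplit(sequence, "")[[1]]]), collapse = "")
}

# --- registry serialization -------------------------------------------------

#' Export / import the registry as JSON, and strands as FASTA
#'
#' `registry_to_json()` serializes the full registry (strands, numbering,
#' constructs and reference pairs) to a JSON file; `registry_from_json()`
#' restores it losslessly.  `write_strand_fasta()` writes the strand
#' sequences as a FASTA file, one record per strand.
#'
#' @param registry an `asite_registry` (or any list of [rna_strand] /
#'   [rna_construct] objects).
#' @param path output/input file path.
#' @return `registry_from_json()` returns the restored registry;
#'   the writers return `path` invisibly.
#' @export
registry_to_json <- function(registry, path) {
  enc <- lapply(registry, function(el) {
    if (inherits(el, "rna_strand")) {
      c(list(.type = "rna_strand"), unclass(el))
    } else if (inherits(el, "rna_construct")) {
      list(.type = "rna_construct", strandA = el$strandA$id,
           strandB = el$strandB$id,
           reference_pairs = lapply(seq_len(nrow(el$reference_pairs)),
                                    function(i) as.integer(el$reference_pairs[i, ])),
           label = el$label)
    } else el
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- list()
  for (nm in names(raw)) {
    el <- raw[[nm]]
    if (identical(el$.type, "rna_strand")) {
      reg[[nm]] <- rna_strand(el$id, el$sequence, el$chemistry,
                              unlist(el$numbering))
    }
  }
  for (nm in names(raw)) {
    el <- raw[[nm]]
    if (identical(el$.type, "rna_construct")) {
      rp <- do.call(rbind, lapply(el$reference_pairs, unlist))
      reg[[nm]] <- rna_construct(reg[[el$strandA]], reg[[el$strandB]],
                                 rp, el$label)
    }
  }
  class(reg) <- "asite_registry"
  reg
}

#' @rdname registry_to_json
#' @export
write_strand_fasta <- function(registry, path) {
  strands <- Filter(function(el) inherits(el, "rna_strand"), registry)
  seqinr::write.fasta(lapply(strands, function(s) strsplit(s$sequence, "")[[1]]),
                      names = vapply(strands, `[[`, "", "id"),
                      file.out = path)
  invisible(path)
}
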