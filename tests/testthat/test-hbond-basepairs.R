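test_that("hydrogen-bond criteria are enforced exactly", {
  # collinear donor-H...acceptor at 2.9 A passes
  expect_equal(nrow(detect_hbonds(make_micro_hbond_traj(2.9, 179.9))), 1)
  # donor-acceptor distance 3.6 A fails
  expect_equal(nrow(detect_hbonds(make_micro_hbond_traj(3.6, 179.9))), 0)
  # angle 140 deg at 2.9 A fails
  expect_equal(nrow(detect_hbonds(make_micro_hbond_traj(2.9, 140))), 0)
  # boundary: 150 deg / 3.5 A still accepted
  expect_equal(nrow(detect_hbonds(make_micro_hbond_traj(3.49, 150.5))), 1)
})

test_that("template pairs give the canonical bond inventories", {
  au <- make_pair_traj("AU")
  hb <- detect_hbonds(au)
  expect_equal(nrow(hb), 2)
  expect_setequal(paste(hb$don_atom, hb$acc_atom),
                  c("N6 O4", "N3 N1"))
  gc <- make_pair_traj("GC")
  hbg <- detect_hbonds(gc)
  expect_equal(nrow(hbg), 3)
  expect_setequal(paste(hbg$don_atom, hbg$acc_atom),
                  c("N1 N3", "N2 O2", "N4 O6"))
  # displacing the partner by 0.8 A breaks both A:U bonds
  shifted <- make_pair_traj("AU", shift_Y = c(0.8, 0, 0))
  expect_equal(nrow(detect_hbonds(shifted)), 0)
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  frame <- fx_prok_frame()
  hb0 <- detect_hbonds(frame)
  rot <- asitetools:::rot_axis(49, c(2, 1, -1), c(5, 5, 5))
  xyz <- asitetools:::apply_rot(get_frame(frame, 1), rot)
  xyz <- sweep(xyz, 2, c(-3, 9, 2), "+")
  moved <- rna_trajectory(frame$topology, array(xyz, c(nrow(xyz), 3, 1)))
  hb1 <- detect_hbonds(moved)
  expect_equal(nrow(hb1), nrow(hb0))
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-9)
})

test_that("edge classification covers WC, Hoogsteen and corner-ambiguous pairs", {
  gc <- make_pair_traj("GC")
  rec <- classify_base_pair(gc, "X1", "Y1")
  expect_equal(rec$type, "WC/WC")
  expect_true(rec$is_wcwc)
  expect_equal(nrow(rec$hbonds), 3)
  # Hoogsteen A:U -> A interacts through its Hoogsteen edge
  hg <- make_pair_traj("AUHG")
  rhg <- classify_base_pair(hg, "X1", "Y1")
  expect_equal(rhg$edge_i, "HG")
  expect_equal(rhg$edge_j, "WC")
  expect_false(rhg$is_wcwc)
  # a single bond through a corner atom yields the asterisk type
  hb <- detect_hbonds(gc)
  single <- hb[hb$don_atom == "N4", , drop = FALSE]  # C N4-H...O6 G
  ramb <- classify_base_pair(gc, "X1", "Y1", hbonds = single)
  expect_equal(ramb$edge_i, "WC*HG")   # G via O6 (WC/HG corner)
  expect_equal(ramb$edge_j, "WC*HG")   # C via N4 (WC/HG corner)
  expect_false(ramb$is_wcwc)
  # no H-bonds -> no pair record
  far <- make_pair_traj("AU", shift_Y = c(30, 0, 0))
  expect_null(classify_base_pair(far, "X1", "Y1"))
  expect_error(classify_base_pair(gc, "X1", "X1"), "differ")
})

test_that("WC-WC and non-WC-WC counters split the bond inventory", {
  frame <- fx_prok_frame()
  con <- frame$construct
  rp <- con$reference_pairs
  la <- strsplit(con$strandA$sequence, "")[[1]]
  b_expected <- sum(ifelse(la[rp[, 1]] %in% c("G", "C"), 3L, 2L))
  expect_equal(count_wcwc_hbonds(frame), b_expected)
  expect_equal(count_nonwcwc_hbonds(frame), 0)
  # appending a Hoogsteen A:U pair far from the duplex adds 2 non-WC bonds
  hgt <- make_pair_traj("AUHG")
  off <- sweep(get_frame(hgt, 1), 2, c(150, 0, 0), "+")
  tp2 <- hgt$topology
  tp2$resno <- tp2$resno + max(frame$topology$resno)
  tp2$pos <- tp2$pos + 100
  tp2$label <- paste0("far_", tp2$label)
  tp <- rbind(frame$topology, tp2)
  tp$eleno <- seq_len(nrow(tp))
  aug <- rna_trajectory(tp, array(rbind(get_frame(frame, 1), off),
                                  c(nrow(tp), 3, 1)))
  expect_equal(count_wcwc_hbonds(aug), b_expected)
  expect_equal(count_nonwcwc_hbonds(aug), 2)
  # empty frame
  empty <- make_pair_traj("AU", shift_Y = c(40, 0, 0))
  expect_equal(count_wcwc_hbonds(empty), 0)
  expect_equal(count_nonwcwc_hbonds(empty), 0)
})

test_that("occupancy tables honour the reporting threshold", {
  reg <- fx_registry()
  # persistent pair -> 100 %
  tr <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0,
                                 nframes = 3, seed = 1)
  occ <- pair_occupancy(tr)
  row <- occ$report[occ$report$pair_i == "C1407" & occ$report$pair_j == "G1494", ]
  expect_equal(row$fraction, 1)
  # a pair present in 1/25 frames (4 %) stays in the table, not the report
  states <- c(rep(TRUE, 24), FALSE)   # flipped out 96 % of the time
  tr2 <- generate_flip_trajectory(
    reg$prokaryotic, list(flip_schedule("G1497", 0.96, "major",
                                        states = states)),
    jitter_sd = 0, nframes = 25, seed = 1)
  occ2 <- pair_occupancy(tr2, threshold = 0.05)
  tab <- occ2$table
  hit <- tab[tab$pair_i == "C1404" & tab$pair_j == "G1497" &
               tab$type == "WC/WC", ]
  expect_equal(hit$fraction, 0.04)
  expect_false(any(occ2$report$pair_i == "C1404" &
                     occ2$report$pair_j == "G1497" &
                     occ2$report$type == "WC/WC"))
  # fractions over all types of one residue pair never exceed 1
  agg <- tapply(tab$fraction, paste(tab$pair_i, tab$pair_j), sum)
  expect_true(all(agg <= 1 + 1e-12))
})

test_that("missing polar hydrogens are reconstructed at idealized positions", {
  frame <- fx_prok_frame()
  tp <- frame$topology
  keep <- tp$element != "H"
  stripped <- rna_trajectory(transform(tp[keep, ], eleno = seq_len(sum(keep))),
                             array(get_frame(frame, 1)[keep, ],
                                   c(sum(keep), 3, 1)))
  # without hydrogens every donor is skipped (with warnings)
  expect_warning(hb0 <- detect_hbonds(stripped), "without hydrogens")
  expect_equal(nrow(hb0), 0)
  rebuilt <- place_hydrogens(stripped)
  expect_equal(nrow(detect_hbonds(rebuilt)), nrow(detect_hbonds(frame)))
  expect_equal(count_wcwc_hbonds(rebuilt), count_wcwc_hbonds(frame))
})
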