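test_that("stacking detection follows the geometric criteria", {
  frame <- fx_prok_frame()
  st <- detect_stacked(frame)
  key <- paste(st$res_i, st$res_j)
  # consecutive intra-strand bases of the regular helix are stacked
  # (both residues reference-paired one lattice level apart; bulge-offset
  # residues legitimately sit outside the stacking register)
  tp <- frame$topology
  pairedA <- sort(frame$construct$reference_pairs[, 1])
  for (p in pairedA[-length(pairedA)]) {
    if (!(p + 1) %in% pairedA) next
    ri <- unique(tp$resno[tp$strand == "A" & tp$pos == p])
    rj <- unique(tp$resno[tp$strand == "A" & tp$pos == p + 1])
    expect_true(paste(ri, rj) %in% key, info = p)
  }
  # Watson-Crick partners are excluded even though centroids may be close
  con <- frame$construct
  for (k in seq_len(nrow(con$reference_pairs))) {
    ri <- con$reference_pairs[k, 1]
    rj <- nchar(con$strandA$sequence) + con$reference_pairs[k, 2]
    expect_false(paste(ri, rj) %in% key)
  }
  # distant bases are not stacked: residues ~ 15 levels apart
  resA <- unique(tp$resno[tp$strand == "A"])
  expect_false(paste(resA[1], resA[15]) %in% key)
  # coplanar side-by-side bases (angle 0, centroid 6 A) are not stacked
  side <- make_pair_traj("AU", shift_Y = c(2, 0, 0)) # pushes centroids apart
  xy <- get_frame(side, 1)
  c1 <- colMeans(xy[side$topology$resno == 1 &
                      side$topology$elety %in% asitetools:::RING6_ATOMS, ])
  c2 <- colMeans(xy[side$topology$resno == 2 &
                      side$topology$elety %in% asitetools:::RING6_ATOMS, ])
  expect_gt(sqrt(sum((c1 - c2)^2)), 4.5)
  expect_equal(nrow(detect_stacked(side)), 0)
})

test_that("stack energies match a brute-force double loop and scaling laws", {
  frame <- fx_prok_frame()
  params <- load_ff_params()
  st <- detect_stacked(frame)
  for (k in seq_len(min(6, nrow(st)))) {
    ours <- stack_energy(frame, st$res_i[k], st$res_j[k], params = params)
    oracle <- brute_stack_energy(frame, st$res_i[k], st$res_j[k], 1, params)
    expect_lt(abs(ours$coulomb - oracle$coulomb), 1e-9)
    expect_lt(abs(ours$vdw - oracle$vdw), 1e-9)
    expect_equal(ours$total, ours$coulomb + ours$vdw)
  }
  # zeroed charges kill the Coulomb term
  p0 <- transform(params, charge = 0)
  e0 <- stack_energy(frame, st$res_i[1], st$res_j[1], params = p0)
  expect_equal(e0$coulomb, 0)
  # doubling all charges quadruples Coulomb and leaves VdW unchanged
  p2 <- transform(params, charge = 2 * charge)
  e1 <- stack_energy(frame, st$res_i[1], st$res_j[1], params = params)
  e2 <- stack_energy(frame, st$res_i[1], st$res_j[1], params = p2)
  expect_equal(e2$coulomb, 4 * e1$coulomb, tolerance = 1e-12)
  expect_equal(e2$vdw, e1$vdw)
  # symmetry in pair order
  eab <- stack_energy(frame, st$res_i[2], st$res_j[2], params = params)
  eba <- stack_energy(frame, st$res_j[2], st$res_i[2], params = params)
  expect_equal(eab$total, eba$total, tolerance = 1e-12)
  # missing parameter is reported by atom (C5 is in every base)
  expect_error(stack_energy(frame, st$res_i[1], st$res_j[1],
                            params = params[params$atom != "C5", ]),
               "C5")
})

test_that("two single atoms at the combined Rmin sit at the LJ minimum", {
  params <- load_ff_params()
  pa <- params[params$restype == "A" & params$atom == "N1", ]
  rmin <- 2 * pa$rmin_half
  tp <- data.frame(eleno = 1:2, elety = "N1", restype = "A", resno = 1:2,
                   strand = "A", pos = 1:2, label = c("r1", "r2"),
                   element = "N", stringsAsFactors = FALSE)
  tr <- rna_trajectory(tp, array(rbind(c(0, 0, 0), c(rmin, 0, 0)),
                                 c(2, 3, 1)))
  p0 <- transform(params, charge = 0)
  e <- stack_energy(tr, 1, 2, params = p0)
  expect_equal(e$vdw, -pa$epsilon, tolerance = 1e-12)
})

test_that("energies are invariant under global rigid motion", {
  frame <- fx_prok_frame()
  st <- detect_stacked(frame)
  e0 <- stack_energy(frame, st$res_i[1], st$res_j[1])
  xyz <- get_frame(frame, 1)
  rot <- asitetools:::rot_axis(33, c(0, 1, 1), c(2, 2, 2))
  moved <- rna_trajectory(frame$topology,
                          array(sweep(asitetools:::apply_rot(xyz, rot), 2,
                                      c(5, -5, 5), "+"),
                                c(nrow(xyz), 3, 1)))
  e1 <- stack_energy(moved, st$res_i[1], st$res_j[1])
  expect_equal(e1$total, e0$total, tolerance = 1e-9)
})

test_that("region averages follow the 50/50 bookkeeping identity", {
  frame <- fx_prok_frame()
  params <- load_ff_params()
  region <- c("G1489", "U1490", "G1491", "A1492", "A1493", "G1494",
              "U1495", "C1496", "G1497", "U1498")
  ra <- region_average(frame, region, params)
  # static single-frame trajectory: zero spread
  tr2 <- rna_trajectory(frame$topology,
                        array(rep(get_frame(frame, 1), 2),
                              c(nrow(frame$topology), 3, 2)))
  ra2 <- region_average(tr2, region, params)
  expect_equal(ra2$total_sd, 0)
  expect_equal(ra2$total_mean, ra$total_mean)
  # oracle: sum pair energies once, half-weight for boundary pairs
  st <- asitetools:::frame_stack_energies(frame, 1, params)
  rg <- vapply(region, function(r) asitetools:::resolve_residue(frame, r), 0L)
  w <- (st$res_i %in% rg) + (st$res_j %in% rg)
  expect_equal(ra$total_mean, sum(0.5 * w * st$total) / length(rg),
               tolerance = 1e-12)
  expect_equal(ra$coulomb_mean + ra$vdw_mean, ra$total_mean,
               tolerance = 1e-12)
})

test_that("stacking time series aggregates windows correctly", {
  reg <- fx_registry()
  tr <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.05,
                                 nframes = 6, seed = 17)
  params <- load_ff_params()
  raw <- stacking_timeseries(tr, params, window = 1)
  expect_equal(nrow(raw), 6)
  w2 <- stacking_timeseries(tr, params, window = 2)
  expect_equal(w2$total, colMeans(matrix(raw$total, nrow = 2)))
  wN <- stacking_timeseries(tr, params, window = 6)
  expect_equal(wN$total, mean(raw$total))
  # oracle re-computation of one frame total
  st <- asitetools:::frame_stack_energies(tr, 3, params)
  tot <- sum(vapply(seq_len(nrow(st)), function(k)
    brute_stack_energy(tr, st$res_i[k], st$res_j[k], 3, params)$total, 0))
  expect_equal(raw$total[3], tot, tolerance = 1e-9)
})
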