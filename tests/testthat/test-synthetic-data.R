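test_that("ideal duplex frames satisfy the hydrogen-bond criteria by construction", {
  for (frame in list(fx_prok_frame(), fx_euk_frame())) {
    con <- frame$construct
    pairs <- asitetools:::classify_frame_pairs(frame)
    rp <- con$reference_pairs
    # every reference pair is detected as WC/WC with the canonical bond count
    la <- strsplit(con$strandA$sequence, "")[[1]]
    for (k in seq_len(nrow(rp))) {
      ri <- rp[k, 1]                       # resno of strand A residue = posA
      rj <- nchar(con$strandA$sequence) + rp[k, 2]
      row <- pairs[pairs$res_i == ri & pairs$res_j == rj, ]
      expect_equal(nrow(row), 1)
      expect_true(row$is_wcwc)
      expect_equal(row$n_hbonds, if (la[ri] %in% c("G", "C")) 3L else 2L)
    }
    # and nothing else is paired in the ideal geometry
    expect_equal(nrow(pairs), nrow(rp))
  }
})

test_that("ideal duplex geometry is deterministic and intra-helical", {
  f1 <- generate_duplex_frame(fx_registry()$prokaryotic)
  f2 <- fx_prok_frame()
  expect_identical(f1$coords, f2$coords)
  # every residue with a defined flip angle is intra-helical
  frame <- fx_prok_frame()
  for (rn in unique(frame$topology$resno)) {
    ang <- tryCatch(pseudo_dihedral(frame, rn), error = function(e) NULL)
    if (is.null(ang)) next
    expect_lt(abs(ang), 50)
  }
})

test_that("flip trajectories realize their schedules exactly at zero jitter", {
  reg <- fx_registry()
  tr <- generate_flip_trajectory(
    reg$prokaryotic,
    list(flip_schedule("U1498", fraction_out = 0.4, groove = "major")),
    jitter_sd = 0, nframes = 10, seed = 11)
  cl <- classify_flip(pseudo_dihedral(tr, "U1498"))
  expect_equal(unname(attr(cl, "fractions")["out"]), 0.4)
  expect_true(all(cl$groove[cl$state == "out"] == "major"))
  expect_true(all(abs(cl$angle[cl$state == "out"]) >= 140))
  # minor-groove flips have positive angles
  trm <- generate_flip_trajectory(
    reg$prokaryotic, list(flip_schedule("A1493", 0.5, "minor")),
    jitter_sd = 0, nframes = 4, seed = 1)
  clm <- classify_flip(pseudo_dihedral(trm, "A1493"))
  expect_true(all(clm$angle[clm$state == "out"] > 0))
})

test_that("unscheduled zero-jitter trajectories are static; seeds reproduce", {
  reg <- fx_registry()
  tr <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0,
                                 nframes = 4, seed = 5)
  expect_equal(max(abs(sweep(tr$coords, c(1, 2), tr$coords[, , 1]))), 0)
  t1 <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.3,
                                 nframes = 3, seed = 5)
  t2 <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.3,
                                 nframes = 3, seed = 5)
  t3 <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.3,
                                 nframes = 3, seed = 6)
  expect_identical(t1$coords, t2$coords)
  expect_false(identical(t1$coords, t3$coords))
  expect_error(generate_flip_trajectory(
    reg$prokaryotic, list(flip_schedule("Z9999", 0.5)), nframes = 2),
    "unknown")
})

test_that("a flipped-out residue breaks its reference pair for those frames", {
  reg <- fx_registry()
  tr <- generate_flip_trajectory(
    reg$prokaryotic, list(flip_schedule("G1497", 0.9, "major")),
    jitter_sd = 0, nframes = 10, seed = 2)
  occ <- pair_occupancy(tr, threshold = 0.05)
  row <- occ$table[occ$table$pair_i == "C1404" & occ$table$pair_j == "G1497" &
                     occ$table$type == "WC/WC", ]
  expect_equal(row$fraction, 0.1)
})

test_that("melting-curve generator matches the two-state model", {
  p <- melt_sim_params(dH = -99.8, TdS = -81.5, c0 = 2e-6,
                       noise_sd = 0)
  cv <- generate_melting_curve(p)
  # far below the melting transition the absorbance equals the folded baseline
  low <- cv$temperature_C <= 12
  base <- p$baseline_folded[1] + p$baseline_folded[2] * cv$temperature_C[low]
  expect_true(all(abs(cv$absorbance[low] - base) / base < 1e-3))
  # f = 0.5 exactly where Ka = 4 / c0
  expect_equal(fraction_from_ka(4 / p$c0, p$c0), 0.5)
  # biphasic sigmoid: fraction spans both plateaus inside 10-90 C
  f <- asitetools:::fraction_from_ka(
    asitetools:::ka_of_temperature(cv$temperature_C + 273.15, p$dH, p$dS), p$c0)
  expect_gt(max(f), 0.99)
  expect_lt(min(f), 0.01)
  # seeded noise reproducible
  pn <- melt_sim_params(dH = -99.8, TdS = -81.5, c0 = 2e-6,
                        noise_sd = 0.003, seed = 4)
  expect_identical(generate_melting_curve(pn)$absorbance,
                   generate_melting_curve(pn)$absorbance)
})

test_that("ITC generator obeys limiting cases and thermodynamic closure", {
  # dH = 0: every heat equals the dilution heat
  s0 <- generate_itc_series(itc_sim_params(ka = 1e7, dH = 0, n = 1,
                                           qdil = -2.5))
  expect_true(all(abs(s0$table$heat_ucal + 2.5) < 1e-12))
  # saturating titration: total binding heat approaches n dH (moles in cell)
  p <- itc_sim_params(ka = 1e9, dH = -50, n = 0.9, cell_conc = 10e-6,
                      syringe_conc = 1e-3, cell_volume = 1.4e-3,
                      injection_volumes = rep(5e-6, 20))
  s <- generate_itc_series(p)
  total_kcal <- sum(s$table$heat_ucal) / 1e9
  expect_lt(abs(total_kcal - p$n * p$dH * p$cell_conc * p$cell_volume) /
              abs(p$n * p$dH * p$cell_conc * p$cell_volume), 0.01)
  # study scheme: sigmoid with inflection near the stoichiometry
  ps <- itc_sim_params(ka = 2.4e7, dH = -115.1, n = 0.89)
  ss <- generate_itc_series(ps)
  h <- ss$table$heat_ucal
  ratio <- cumsum(ps$syringe_conc * ps$injection_volumes) /
    (ps$cell_conc * ps$cell_volume)
  infl <- ratio[which.max(diff(h))]
  expect_lt(abs(infl - ps$n), 0.25)
  expect_true(all(diff(h) > -1e-9))   # exothermic heats decay monotonically
})
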