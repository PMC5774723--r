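test_that("multi-model PDB I/O round-trips generated trajectories", {
  reg <- fx_registry()
  tr <- generate_flip_trajectory(reg$prokaryotic,
                                 list(flip_schedule("U1498", 0.5, "major")),
                                 jitter_sd = 0.05, nframes = 5, seed = 3)
  tf <- tempfile(fileext = ".pdb")
  write_trajectory(tr, tf)
  tr2 <- read_trajectory(tf, reg$prokaryotic)
  expect_equal(n_frames(tr2), 5)
  expect_identical(tr2$topology$elety, tr$topology$elety)  # atom order kept
  expect_identical(tr2$topology$label, tr$topology$label)
  # PDB coordinates are written with 3 decimals
  expect_lt(max(abs(tr2$coords - tr$coords)), 5.1e-4)
  # single-model file reads as one frame
  f1 <- generate_duplex_frame(reg$prokaryotic)
  tf1 <- tempfile(fileext = ".pdb")
  write_trajectory(f1, tf1)
  expect_equal(n_frames(read_trajectory(tf1)), 1)
})

test_that("models with inconsistent atom counts are rejected", {
  reg <- fx_registry()
  f1 <- generate_duplex_frame(reg$prokaryotic)
  tf <- tempfile(fileext = ".pdb")
  write_trajectory(f1, tf)
  atom_rec <- grep("^ATOM", readLines(tf), value = TRUE)
  bad <- c("MODEL        1", atom_rec, "ENDMDL",
           "MODEL        2", atom_rec[-1], "ENDMDL", "END")
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(bad, tf2)
  expect_error(suppressWarnings(read_trajectory(tf2)))
})

test_that("Kabsch RMSD is exact on rigid motions and matches oracles", {
  reg <- fx_registry()
  xyz <- get_frame(fx_prok_frame(), 1)
  expect_equal(kabsch_rmsd(xyz, xyz), 0)
  rot <- asitetools:::rot_axis(63, c(1, -2, 0.5), c(10, 3, -8))
  moved <- asitetools:::apply_rot(xyz, rot)
  moved <- sweep(moved, 2, c(4, -7, 11), "+")
  expect_lt(kabsch_rmsd(xyz, moved), 1e-6)
  # 3-atom toy against a brute-force grid search over rotations
  A <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2, 0))
  B <- rbind(c(0.2, 0.1, 0), c(1.4, 0.3, 0.4), c(-0.3, 1.8, 0.1))
  cA <- sweep(A, 2, colMeans(A)); cB <- sweep(B, 2, colMeans(B))
  rmsd_euler <- function(ang) {
    R <- asitetools:::rot_axis(ang[1], c(0, 0, 1))$R %*%
      asitetools:::rot_axis(ang[2], c(0, 1, 0))$R %*%
      asitetools:::rot_axis(ang[3], c(1, 0, 0))$R
    sqrt(mean(rowSums((cA %*% t(R) - cB)^2)))
  }
  grid_best <- Inf; grid_arg <- c(0, 0, 0)
  for (a in seq(0, 350, by = 10)) for (b in seq(0, 350, by = 10))
    for (g in seq(0, 350, by = 10)) {
      v <- rmsd_euler(c(a, b, g))
      if (v < grid_best) { grid_best <- v; grid_arg <- c(a, b, g) }
    }
  # refine the coarse direct search locally (still independent of Kabsch)
  ref <- optim(grid_arg, rmsd_euler, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  expect_lt(abs(kabsch_rmsd(A, B) - ref$value), 1e-3)
  # independent implementation agrees
  tr <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.4,
                                 nframes = 2, seed = 8)
  ours <- kabsch_rmsd(get_frame(tr, 1), get_frame(tr, 2))
  theirs <- bio3d::rmsd(as.numeric(t(get_frame(tr, 1))),
                        as.numeric(t(get_frame(tr, 2))), fit = TRUE)
  expect_lt(abs(ours - theirs), 1e-3)
  expect_error(kabsch_rmsd(xyz, moved, selection = integer(0)), "empty")
  expect_error(kabsch_rmsd(xyz, moved[-1, ]), "differ")
})

test_that("RMSD is a pseudo-metric on random synthetic frames", {
  reg <- fx_registry()
  tr <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.5,
                                 nframes = 6, seed = 21)
  M <- pairwise_rmsd(tr)
  expect_true(all(abs(M - t(M)) < 1e-12))
  expect_true(all(diag(M) == 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(M[i, j], M[i, k] + M[k, j] + 1e-9)
})

test_that("RMSF recovers closed-form displacements and flip mobility", {
  frame <- fx_prok_frame()
  xyz <- get_frame(frame, 1)
  d <- 0.8
  res5 <- which(frame$topology$resno == 5)
  x2 <- xyz; x2[res5, 1] <- x2[res5, 1] + d
  x3 <- xyz; x3[res5, 1] <- x3[res5, 1] - d
  tr <- rna_trajectory(frame$topology,
                       array(c(x2, x3), c(nrow(xyz), 3, 2)))
  rf <- rmsf(tr, fit = FALSE)
  expect_equal(rf$rmsf[rf$resno == 5], d, tolerance = 1e-12)
  expect_true(all(rf$rmsf[rf$resno != 5] == 0))
  # with superposition the displaced residue still dominates
  rf2 <- rmsf(tr)
  expect_equal(which.max(rf2$rmsf), which(rf2$resno == 5))
  # a flipping residue has the greatest RMSF in a schedule trajectory
  trf <- generate_flip_trajectory(fx_registry()$prokaryotic,
                                  list(flip_schedule("U1498", 0.5, "major")),
                                  jitter_sd = 0, nframes = 6, seed = 2)
  rff <- rmsf(trf)
  expect_equal(rff$label[which.max(rff$rmsf)], "U1498")
  expect_error(rmsf(fx_prok_frame()), "two frames")
})

test_that("gromos clustering partitions frames with exact membership", {
  reg <- fx_registry()
  trA <- generate_flip_trajectory(reg$prokaryotic, list(), jitter_sd = 0.01,
                                  nframes = 4, seed = 1)
  trB <- generate_flip_trajectory(
    reg$prokaryotic,
    list(flip_schedule("U1498", 1, "major"), flip_schedule("A1493", 1, "minor")),
    jitter_sd = 0.01, nframes = 3, seed = 2)
  comb <- rna_trajectory(trA$topology,
                         array(c(trA$coords, trB$coords),
                               c(dim(trA$coords)[1], 3, 7)))
  cl <- gromos_cluster(comb, cutoff = 1.0)
  expect_equal(length(cl$sizes), 2)
  expect_equal(cl$assignments, c(1, 1, 1, 1, 2, 2, 2))
  expect_equal(sum(cl$sizes), 7)
  # every centre belongs to its own cluster
  for (c_id in seq_along(cl$centers))
    expect_equal(cl$assignments[match(cl$centers[c_id], cl$frames)], c_id)
  # one cluster when the cutoff dominates all distances
  cl1 <- gromos_cluster(comb, cutoff = 1e3)
  expect_equal(cl1$sizes, 7L)
  # cluster count is non-increasing as the cutoff grows
  M <- pairwise_rmsd(comb)
  ns <- vapply(c(0.05, 0.5, 1.0, 3.0),
               function(co) length(gromos_cluster(M, co)$sizes), 0L)
  expect_true(all(diff(ns) <= 0))
  # deterministic re-run
  expect_identical(gromos_cluster(M, 1.0), gromos_cluster(M, 1.0))
  expect_error(gromos_cluster(comb, cutoff = 0), "cutoff")
})

test_that("block standard error matches closed forms", {
  expect_error(block_standard_error(c(1, 2, 3)), "too short")
  # constant series
  b0 <- block_standard_error(rep(2.5, 64))
  expect_true(all(b0$bse == 0))
  expect_equal(b0$block_size, 2^(0:4))
  # BSE(1) = sd / sqrt(N)
  set.seed(9); x <- rnorm(4096)
  b <- block_standard_error(x)
  expect_equal(b$bse[1], sd(x) / sqrt(4096))
  # iid: flat curve at sigma/sqrt(N) within 3x Monte Carlo error
  mc <- 3 * b$bse / sqrt(2 * (b$n_blocks - 1))
  expect_true(all(abs(b$bse - sd(x) / sqrt(4096)) <= 3 * mc + 2e-4))
  # AR(1): plateau near sigma sqrt((1+rho)/(1-rho)) / sqrt(N)
  rho <- 0.9; n <- 16384
  set.seed(7)
  ar <- as.numeric(arima.sim(list(ar = rho), n, sd = 1))
  bar <- block_standard_error(ar)
  plateau <- mean(bar$bse[bar$block_size %in% c(256, 512, 1024)])
  theory <- sd(ar) * sqrt((1 + rho) / (1 - rho)) / sqrt(n)
  expect_lt(abs(plateau - theory) / theory, 0.35)
  # monotone non-decreasing in expectation for positively correlated series
  set.seed(13)
  mono <- replicate(8, {
    y <- as.numeric(arima.sim(list(ar = 0.8), 2048, sd = 1))
    bb <- block_standard_error(y)
    mean(diff(bb$bse) >= 0)
  })
  expect_gt(mean(mono), 0.8)
})

test_that("the two-exponential block-average model tracks an AR(1) curve", {
  set.seed(31)
  ar <- as.numeric(arima.sim(list(ar = 0.8), 8192, sd = 1))
  b <- block_standard_error(ar)
  fit <- fit_bse_two_exp(b)
  expect_lt(sqrt(fit$sse / nrow(b)) / max(b$bse), 0.15)
})
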