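# Shared fixtures (cached across tests) and independent brute-force oracles.

fixture_env <- new.env()

fx_registry <- function() {
  if (is.null(fixture_env$reg)) fixture_env$reg <- build_registry()
  fixture_env$reg
}

fx_prok_frame <- function() {
  if (is.null(fixture_env$prok_frame))
    fixture_env$prok_frame <- generate_duplex_frame(fx_registry()$prokaryotic)
  fixture_env$prok_frame
}

fx_euk_frame <- function() {
  if (is.null(fixture_env$euk_frame))
    fixture_env$euk_frame <- generate_duplex_frame(fx_registry()$eukaryotic)
  fixture_env$euk_frame
}

# two-residue trajectory from a packaged pair template (X = residue 1)
make_pair_traj <- function(pairtype = "AU", shift_Y = c(0, 0, 0)) {
  tX <- asitetools:::template_nucleotide(pairtype, "X")
  tY <- asitetools:::template_nucleotide(pairtype, "Y")
  tY <- sweep(tY, 2, shift_Y, "+")
  rt <- function(m, rn, strand, pos, label) data.frame(
    eleno = NA, elety = rownames(m), restype = label0(pairtype, rn),
    resno = rn, strand = strand, pos = pos,
    label = label, element = asitetools:::element_of(rownames(m)),
    stringsAsFactors = FALSE)
  label0 <- function(pt, rn) {
    if (pt == "AUHG") c("A", "U")[rn] else substr(pt, rn, rn)
  }
  tp <- rbind(rt(tX, 1, "A", 1, "X1"), rt(tY, 2, "B", 1, "Y1"))
  tp$eleno <- seq_len(nrow(tp))
  rna_trajectory(tp, array(rbind(tX, tY), c(nrow(tp), 3, 1)))
}

# minimal donor/acceptor fixture: residue 1 = U (N3-H3), residue 2 = A (N1
# acceptor placed at distance `dist` and A..H-D angle `angle_deg`)
make_micro_hbond_traj <- function(dist, angle_deg) {
  D <- c(0, 0, 0)
  H <- c(1.01, 0, 0)
  th <- angle_deg * pi / 180
  u <- c(cos(pi - th), sin(pi - th), 0)   # direction from H, angle at H
  # solve |H + t u - D| = dist
  b <- 2 * sum(u * H)
  cc <- sum(H^2) - dist^2
  t <- (-b + sqrt(b^2 - 4 * cc)) / 2
  A <- H + t * u
  tp <- data.frame(
    eleno = 1:3, elety = c("N3", "H3", "N1"), restype = c("U", "U", "A"),
    resno = c(1, 1, 2), strand = c("A", "A", "B"), pos = c(1, 1, 1),
    label = c("U1", "U1", "A1"), element = c("N", "H", "N"),
    stringsAsFactors = FALSE)
  rna_trajectory(tp, array(rbind(D, H, A), c(3, 3, 1)))
}

# independent brute-force stacking energy: plain double loop over atoms
brute_stack_energy <- function(traj, i, j, frame, params = load_ff_params()) {
  tp <- traj$topology
  xyz <- get_frame(traj, frame)
  ri <- asitetools:::resolve_residue(traj, i)
  rj <- asitetools:::resolve_residue(traj, j)
  idx <- function(rn) {
    rows <- tp[tp$resno == rn, ]
    rows$eleno[rows$elety %in% asitetools:::BASE_ATOMS[[rows$restype[1]]]]
  }
  par_of <- function(k) {
    params[params$restype == tp$restype[k] & params$atom == tp$elety[k], ]
  }
  coul <- 0; vdw <- 0
  for (a in idx(ri)) for (b in idx(rj)) {
    pa <- par_of(a); pb <- par_of(b)
    r <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    coul <- coul + 332.0636 * pa$charge * pb$charge / r
    eps <- sqrt(pa$epsilon * pb$epsilon)
    rmin <- pa$rmin_half + pb$rmin_half
    vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  list(coulomb = coul, vdw = vdw, total = coul + vdw)
}

# closed-form OLS via the normal equations
ols_slope_intercept <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# brute-force antiparallel mismatch scan (independent of the package path)
brute_mismatches <- function(oligo_seq, target_seq) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  lo <- strsplit(oligo_seq, "")[[1]]
  lt <- strsplit(target_seq, "")[[1]]
  L <- length(lo)
  best <- Inf
  for (w in seq_len(length(lt) - L + 1)) {
    mm <- 0
    for (k in seq_len(L))
      if (comp[[lo[k]]] != lt[w + L - k]) mm <- mm + 1
    best <- min(best, mm)
  }
  best
}
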