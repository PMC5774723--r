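# Builds the idealized A-form nucleotide templates shipped as
# inst/extdata/aform_templates.csv (run from the package root).  Bases are planar idealized rings; the
# complementary base of each canonical pair is placed by least squares so that
# every Watson-Crick hydrogen bond satisfies d(D..A) <= 3.5 A and
# angle(A-H-D) >= 150 deg by construction.  A schematic sugar-phosphate
# backbone is attached in a per-residue local frame; the phosphate offset is
# tuned so the base-flip pseudo-dihedral of intra-helical residues sits near 0.

rot2 <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

radial_out <- function(ring, atom, bond) {
  v <- ring[atom, ]
  v * (sqrt(sum(v^2)) + bond) / sqrt(sum(v^2))
}

# two in-plane hydrogens of an amine N, +-60 deg off the outward radial
amine_h <- function(pos_n, center = c(0, 0)) {
  u <- (pos_n - center) / sqrt(sum((pos_n - center)^2))
  list(h1 = pos_n + 1.01 * as.vector(rot2(60) %*% u),
       h2 = pos_n + 1.01 * as.vector(rot2(-60) %*% u))
}

make_pyrimidine <- function(type = c("C", "U")) {
  type <- match.arg(type)
  ang <- (seq(-90, by = 60, length.out = 6)) * pi / 180
  R <- 1.39
  ring <- cbind(R * cos(ang), R * sin(ang))
  rownames(ring) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  atoms <- ring
  atoms <- rbind(atoms, O2 = radial_out(ring, "C2", 1.23))
  if (type == "C") {
    atoms <- rbind(atoms, N4 = radial_out(ring, "C4", 1.34))
    h <- amine_h(atoms["N4", ])
    atoms <- rbind(atoms, H41 = h$h1, H42 = h$h2)
  } else {
    atoms <- rbind(atoms, O4 = radial_out(ring, "C4", 1.23))
    atoms <- rbind(atoms, H3 = radial_out(ring, "N3", R + 1.01 - R) * NA) # placeholder
    atoms["H3", ] <- ring["N3", ] * (R + 1.01) / R
  }
  atoms
}

make_purine <- function(type = c("A", "G")) {
  type <- match.arg(type)
  ang <- (seq(90, by = 60, length.out = 6)) * pi / 180
  R <- 1.39
  ring <- cbind(R * cos(ang), R * sin(ang))
  rownames(ring) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  # five-membered ring fused at the C4-C5 edge, on the side away from origin
  s <- 1.39
  M <- (ring["C4", ] + ring["C5", ]) / 2
  u <- M / sqrt(sum(M^2))
  apothem <- s / (2 * tan(pi / 5))
  r5 <- s / (2 * sin(pi / 5))
  cen5 <- M + apothem * u
  a4 <- atan2(ring["C4", 2] - cen5[2], ring["C4", 1] - cen5[1])
  a5 <- atan2(ring["C5", 2] - cen5[2], ring["C5", 1] - cen5[1])
  # choose step direction so that 4 steps from C4 reaches C5
  step <- 2 * pi / 5
  dirs <- c(1, -1)
  pick <- dirs[which.min(abs(sapply(dirs, function(d)
    Arg(exp(1i * (a4 + 4 * d * step - a5))))))]
  penta <- sapply(1:3, function(k) {
    th <- a4 + pick * k * step
    cen5 + r5 * c(cos(th), sin(th))
  })
  atoms <- rbind(ring,
                 N9 = penta[, 1], C8 = penta[, 2], N7 = penta[, 3])
  if (type == "A") {
    atoms <- rbind(atoms, N6 = radial_out(ring, "C6", 1.34))
    h <- amine_h(atoms["N6", ])
    atoms <- rbind(atoms, H61 = h$h1, H62 = h$h2)
  } else {
    atoms <- rbind(atoms, O6 = radial_out(ring, "C6", 1.23),
                   N2 = radial_out(ring, "C2", 1.34))
    atoms <- rbind(atoms, H1 = ring["N1", ] * (R + 1.01) / R)
    h <- amine_h(atoms["N2", ])
    atoms <- rbind(atoms, H21 = h$h1, H22 = h$h2)
  }
  atoms
}

BASES2D <- list(A = make_purine("A"), G = make_purine("G"),
                C = make_pyrimidine("C"), U = make_pyrimidine("U"))

DONOR_H <- list(N6 = c("H61", "H62"), N4 = c("H41", "H42"),
                N2 = c("H21", "H22"), N1 = "H1", N3 = "H3")

# --- pair placement ---------------------------------------------------------
# X stays put; Y is mirrored in-plane (y -> -y, i.e. 180 deg about x so the
# glycosidic geometry is antiparallel) then rotated/translated to bring each
# donor..acceptor contact to 2.90 A with a near-linear hydrogen.

hb_angle <- function(a, h, d) {
  v1 <- a - h; v2 <- d - h
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

# rigid 2D Procrustes: rotation+translation mapping A onto B (no scaling)
procrustes2d <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t0 <- cb - as.vector(R %*% ca)
  c(theta, t0)
}

place_pair <- function(x_atoms, y_atoms, contacts, x_type, y_type) {
  res <- lapply(list(diag(c(1, -1)), diag(2)), function(mir)
    place_pair_one(x_atoms, y_atoms %*% mir, contacts, x_type, y_type))
  res[[which.min(sapply(res, `[[`, "value"))]]
}

place_pair_one <- function(x_atoms, flipY, contacts, x_type, y_type) {
  rownames(flipY) <- rownames(flipY)
  obj <- function(p) {
    Ty <- t(rot2(p[1]) %*% t(flipY)) + rep(1, nrow(flipY)) %o% p[2:3]
    rownames(Ty) <- rownames(flipY)
    s <- 0
    for (ct in contacts) {
      ax <- x_atoms[ct[1], ]; ay <- Ty[ct[2], ]
      s <- s + (sqrt(sum((ax - ay)^2)) - 2.90)^2
      # identify donor side and its hydrogens, reward linear A-H..D
      if (ct[1] %in% names(DONOR_H) && any(DONOR_H[[ct[1]]] %in% rownames(x_atoms)) &&
          !(x_type %in% c("A", "G") && ct[1] == "N1" && x_type == "A")) {
        hs <- intersect(DONOR_H[[ct[1]]], rownames(x_atoms))
        ang <- max(sapply(hs, function(h) hb_angle(ay, x_atoms[h, ], x_atoms[ct[1], ])))
        s <- s + 0.002 * (180 - ang)^2
      }
      if (ct[2] %in% names(DONOR_H) && any(DONOR_H[[ct[2]]] %in% rownames(Ty))) {
        hs <- intersect(DONOR_H[[ct[2]]], rownames(Ty))
        ang <- max(sapply(hs, function(h) hb_angle(ax, Ty[h, ], Ty[ct[2], ])))
        s <- s + 0.002 * (180 - ang)^2
      }
    }
    # soft clash penalty between heavy atoms
    hx <- x_atoms[!grepl("^H", rownames(x_atoms)), , drop = FALSE]
    hy <- Ty[!grepl("^H", rownames(Ty)), , drop = FALSE]
    dm <- as.matrix(dist(rbind(hx, hy)))[seq_len(nrow(hx)), nrow(hx) + seq_len(nrow(hy))]
    s + sum(pmax(0, 2.7 - dm)^2)
  }
  # analytic initial guess: targets for Y contact atoms sit 2.9 A beyond X's
  # contact atoms along the outward edge normal of X
  cx <- t(sapply(contacts, function(ct) x_atoms[ct[1], ]))
  u <- colMeans(cx) / sqrt(sum(colMeans(cx)^2))
  targets <- sweep(cx, 2, 2.9 * u, "+")
  cy <- t(sapply(contacts, function(ct) flipY[ct[2], ]))
  p0 <- procrustes2d(cy, targets)
  best <- NULL
  for (th in c(0, seq(-40, 40, by = 10))) {
    r <- optim(p0 + c(th, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 8000, reltol = 1e-13))
    if (is.null(best) || r$value < best$value) best <- r
  }
  p <- best$par
  Ty <- t(rot2(p[1]) %*% t(flipY)) + rep(1, nrow(flipY)) %o% p[2:3]
  rownames(Ty) <- rownames(flipY)
  list(X = x_atoms, Y = Ty, value = best$value)
}

report_contacts <- function(pr, contacts) {
  for (ct in contacts) {
    d <- sqrt(sum((pr$X[ct[1], ] - pr$Y[ct[2], ])^2))
    cat(sprintf("  %s..%s  d=%.3f", ct[1], ct[2], d))
    for (side in 1:2) {
      don <- ct[side]; tbl <- if (side == 1) pr$X else pr$Y
      oth <- if (side == 1) pr$Y[ct[2], ] else pr$X[ct[1], ]
      if (don %in% names(DONOR_H) && any(DONOR_H[[don]] %in% rownames(tbl))) {
        hs <- intersect(DONOR_H[[don]], rownames(tbl))
        ang <- max(sapply(hs, function(h) hb_angle(oth, tbl[h, ], tbl[don, ])))
        cat(sprintf("  ang(%s-side)=%.1f", c("X", "Y")[side], ang))
      }
    }
    cat("\n")
  }
}

gc <- place_pair(BASES2D$G, BASES2D$C,
                 list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")), "G", "C")
cat("G:C  obj =", gc$value, "\n")
report_contacts(gc, list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")))

au <- place_pair(BASES2D$A, BASES2D$U,
                 list(c("N1", "N3"), c("N6", "O4")), "A", "U")
cat("A:U  obj =", au$value, "\n")
report_contacts(au, list(c("N1", "N3"), c("N6", "O4")))

# Hoogsteen A:U feasibility (fixture for tests; not shipped)
hg <- place_pair(BASES2D$A, BASES2D$U,
                 list(c("N7", "N3"), c("N6", "O4")), "A", "U")
cat("A:U Hoogsteen  obj =", hg$value, "\n")
report_contacts(hg, list(c("N7", "N3"), c("N6", "O4")))

# --- standardize pair frames ------------------------------------------------
heavy_names <- function(m) rownames(m)[!grepl("^H", rownames(m))]

standardize_pair <- function(pr, x_type, y_type) {
  X <- cbind(pr$X, 0); Y <- cbind(pr$Y, 0)
  allh <- rbind(X[heavy_names(X), ], Y[heavy_names(Y), ])
  cen <- colMeans(allh)
  X <- sweep(X, 2, cen); Y <- sweep(Y, 2, cen)
  bx <- colMeans(X[heavy_names(X), ]); by <- colMeans(Y[heavy_names(Y), ])
  v <- by - bx; th <- atan2(v[2], v[1])
  Rz <- matrix(c(cos(-th), sin(-th), 0, -sin(-th), cos(-th), 0, 0, 0, 1), 3, 3)
  list(X = X %*% t(Rz), Y = Y %*% t(Rz))
}

GLYCO <- c(A = "N9", G = "N9", C = "N1", U = "N1")
FRAME_ATOMS <- list(A = c("N9", "C8", "N7"), G = c("N9", "C8", "N7"),
                    C = c("N1", "C2", "N3"), U = c("N1", "C2", "N3"))

base_frame <- function(atoms, type, role) {
  hv <- atoms[heavy_names(atoms), , drop = FALSE]
  cent <- colMeans(hv)
  gl <- atoms[GLYCO[type], ]
  e1 <- gl - cent; e1 <- e1 / sqrt(sum(e1^2))
  fa <- FRAME_ATOMS[[type]]
  v1 <- atoms[fa[2], ] - atoms[fa[1], ]; v2 <- atoms[fa[3], ] - atoms[fa[1], ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  e3 <- if (role == "X") nrm else -nrm
  e1 <- e1 - sum(e1 * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(origin = gl, E = cbind(e1, e2, e3))
}

backbone_offsets <- function(p_off) {
  op1 <- p_off + c(-0.25, 0.95, 1.10)
  op2 <- p_off + c(1.30, 0.65, -0.55)
  rbind("C1'" = c(1.48, 0, 0),
        "C2'" = c(2.35, -0.95, -0.55),
        "O2'" = c(2.10, -2.30, -0.75),
        "HO2'" = c(2.72, -3.02, -0.95),
        "C3'" = c(3.55, -0.60, -0.30),
        "O3'" = c(4.45, -1.55, 0.25),
        "O4'" = c(2.25, 1.05, 0.40),
        "C4'" = c(3.60, 0.75, 0.45),
        "C5'" = c(4.25, 1.75, 1.30),
        "O5'" = (c(4.25, 1.75, 1.30) + p_off) / 2 + c(0, 0.2, 0.2),
        "P" = p_off, "OP1" = op1, "OP2" = op2)
}

add_backbone <- function(atoms, type, role, p_off) {
  fr <- base_frame(atoms, type, role)
  bb <- t(apply(backbone_offsets(p_off), 1, function(o)
    fr$origin + as.vector(fr$E %*% o)))
  rbind(atoms, bb)
}

build_pair_coords <- function(pr, x_type, y_type, p_off) {
  st <- standardize_pair(pr, x_type, y_type)
  list(X = add_backbone(st$X, x_type, "X", p_off),
       Y = add_backbone(st$Y, y_type, "Y", p_off))
}

swap_roles <- function(pc) {
  # 180 deg about y: x -> -x, z -> -z; puts the old Y on the X side
  M <- diag(c(-1, 1, -1))
  list(X = pc$Y %*% M, Y = pc$X %*% M)
}

# --- helix assembly + pseudo-dihedral (scratch copies of package logic) -----
RISE <- 2.81; TWIST <- 32.7

rotz <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

place_at_level <- function(atoms, level) {
  sweep(atoms %*% t(rotz(level * TWIST)), 2, c(0, 0, level * RISE), "+")
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

COMP <- c(A = "U", U = "A", G = "C", C = "G")

# duplex with strand A = seq, strand B = reverse complement; level = index-1
assemble_test_duplex <- function(seqA, pcs) {
  n <- nchar(seqA)
  res <- list()
  for (i in seq_len(n)) {
    xa <- substr(seqA, i, i); yb <- COMP[[xa]]
    pc <- pcs[[paste0(xa, yb)]]
    res[[paste0("A", i)]] <- list(strand = "A", pos = i, type = xa,
                                  atoms = place_at_level(pc$X, i - 1))
    res[[paste0("B", n - i + 1)]] <- list(strand = "B", pos = n - i + 1, type = yb,
                                          atoms = place_at_level(pc$Y, i - 1))
  }
  res
}

base_com <- function(r) {
  ba <- intersect(rownames(BASES2D[[r$type]]), rownames(r$atoms))
  ba <- ba[!grepl("^H", ba)]
  colMeans(r$atoms[ba, , drop = FALSE])
}
phos_com <- function(r) colMeans(r$atoms[c("P", "OP1", "OP2"), ])

pseudo_dihedral_res <- function(res, strand, pos, n) {
  id <- paste0(strand, pos)
  nxt <- paste0(strand, pos + 1)           # 3' neighbour
  lev <- if (strand == "A") pos - 1 else n - pos
  fl1 <- lev - 1; fl2 <- lev + 1
  iv <- colMeans(do.call(rbind, lapply(c(fl1, fl2), function(l) {
    rbind(base_com(res[[paste0("A", l + 1)]]), base_com(res[[paste0("B", n - l)]]))
  })))
  dihedral_deg(base_com(res[[id]]), phos_com(res[[id]]), phos_com(res[[nxt]]), iv)
}

PCS_BASE <- list(
  GC = list(pr = gc, x = "G", y = "C"),
  AU = list(pr = au, x = "A", y = "U"))

eval_p_off <- function(p_off) {
  pcs <- list()
  for (nm in names(PCS_BASE)) {
    b <- PCS_BASE[[nm]]
    pcs[[nm]] <- build_pair_coords(b$pr, b$x, b$y, p_off)
  }
  pcs$CG <- swap_roles(pcs$GC); pcs$UA <- swap_roles(pcs$AU)
  seqA <- "GACGUCAGUC"
  res <- assemble_test_duplex(seqA, pcs)
  n <- nchar(seqA)
  angs <- c()
  for (s in c("A", "B")) for (p in 3:(n - 2))
    angs <- c(angs, pseudo_dihedral_res(res, s, p, n))
  prad <- sqrt(sum(res$A5$atoms["P", 1:2]^2))
  list(angs = angs, prad = prad, pcs = pcs, res = res)
}

if (!exists("SKIP_TUNE") || !SKIP_TUNE) {
  best <- NULL
  for (a in seq(3.5, 6, 0.5)) for (b in seq(-3.5, 3.5, 0.5)) for (cc in seq(-3.5, 3.5, 0.5)) {
    ev <- eval_p_off(c(a, b, cc))
    if (ev$prad < 7 || ev$prad > 11) next
    sc <- max(abs(ev$angs))
    if (is.null(best) || sc < best$sc) best <- list(sc = sc, p = c(a, b, cc), prad = ev$prad)
  }
  cat("best P offset:", best$p, " max|angle|:", round(best$sc, 1),
      " P radius:", round(best$prad, 2), "\n")
}

# --- validation with the chosen offset --------------------------------------
P_OFF <- c(6, -0.5, -2)
ev <- eval_p_off(P_OFF)
cat("intra-helical angle range:", round(range(ev$angs), 2), "\n")

BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", U = "N3")
BASE_ACCEPT <- list(A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
                    C = c("N3", "O2"), U = c("O2", "O4"))
BB_ACCEPT <- c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2")
DONOR_H2 <- c(DONOR_H, list("O2'" = "HO2'"))

find_hbonds <- function(res) {
  out <- NULL
  ids <- names(res)
  for (i in ids) for (j in ids) {
    if (i == j) next
    ri <- res[[i]]; rj <- res[[j]]
    dons <- c(BASE_DONORS[[ri$type]], "O2'")
    accs <- c(BASE_ACCEPT[[rj$type]], BB_ACCEPT)
    for (d in dons) {
      if (!d %in% rownames(ri$atoms)) next
      for (h in DONOR_H2[[d]]) {
        if (!h %in% rownames(ri$atoms)) next
        for (a in accs) {
          if (!a %in% rownames(rj$atoms)) next
          D <- ri$atoms[d, ]; H <- ri$atoms[h, ]; A <- rj$atoms[a, ]
          if (sqrt(sum((D - A)^2)) <= 3.5 && hb_angle(A, H, D) >= 150)
            out <- rbind(out, data.frame(don_res = i, don = d, acc_res = j, acc = a,
                                         dist = sqrt(sum((D - A)^2))))
        }
      }
    }
  }
  out
}

hb <- find_hbonds(ev$res)
cat("\nall H-bonds in 10-bp test duplex:\n")
print(hb, digits = 3)

ring6 <- function(r) colMeans(r$atoms[c("N1","C2","N3","C4","C5","C6"), ])
plane_normal <- function(r) {
  m <- r$atoms[c("N1","C2","N3","C4","C5","C6"), ]
  sv <- svd(sweep(m, 2, colMeans(m)))
  sv$v[, 3]
}
cat("\nconsecutive intra-strand ring6 centroid distances / plane angles:\n")
for (p in 1:9) {
  r1 <- ev$res[[paste0("A", p)]]; r2 <- ev$res[[paste0("A", p + 1)]]
  d <- sqrt(sum((ring6(r1) - ring6(r2))^2))
  ang <- acos(min(1, abs(sum(plane_normal(r1) * plane_normal(r2))))) * 180 / pi
  cat(sprintf("A%d-A%d d=%.2f ang=%.1f   ", p, p + 1, d, ang))
}
cat("\ncross-pair ring6 distance (A5 vs B6):",
    round(sqrt(sum((ring6(ev$res$A5) - ring6(ev$res$B6))^2)), 2), "\n")

# --- freeze templates -------------------------------------------------------
pcs <- ev$pcs
auhg <- build_pair_coords(hg, "A", "U", P_OFF)
pcs$AUHG <- auhg

rows <- NULL
for (nm in names(pcs)) {
  xt <- if (nm == "AUHG") "A" else substr(nm, 1, 1)
  yt <- if (nm == "AUHG") "U" else substr(nm, 2, 2)
  for (role in c("X", "Y")) {
    at <- pcs[[nm]][[role]]
    rt <- if (role == "X") xt else yt
    rows <- rbind(rows, data.frame(pair = nm, role = role, restype = rt,
                                   atom = rownames(at),
                                   x = round(at[, 1], 4), y = round(at[, 2], 4),
                                   z = round(at[, 3], 4)))
  }
}
rownames(rows) <- NULL
write.csv(rows, "/root/pkg/inst/extdata/aform_templates.csv", row.names = FALSE,
          quote = FALSE)
cat("wrote", nrow(rows), "template atom rows\n")
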