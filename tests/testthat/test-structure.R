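test_that("PDB frames round-trip coordinates at format precision", {
  fr <- make_ca_frame(5)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_frame(fr, p)
  rd <- read_pdb_frame(p)
  expect_equal(nrow(rd$atoms), 5L)
  expect_lt(max(abs(rd$coords - fr$coords)), 1e-3 + 1e-12)
  expect_equal(rd$atoms$resno, 1:5)
  expect_error(read_pdb_frame(tempfile()), "no such file")
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA  ALA A   2       3.000   0.000   0.000  1.00 10.00           C",
    "END"), p)
  fr <- read_pdb_frame(p)
  expect_equal(nrow(fr$atoms), 2L)
  expect_equal(fr$coords[fr$atoms$resno == 1, 1], 1.000, tolerance = 1e-6)
})

test_that("Kabsch superposition is exact for rigid motions and matches bio3d", {
  A <- make_ca_frame(10, seed = 5)$coords
  # identity
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  # rotation 37 degrees about z plus translation: rmsd ~ 0
  B <- A %*% rotation_z(37) + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  # collinear set rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")

  # noisy pair: agreement with bio3d's least-squares fit
  set.seed(77)
  for (rep in 1:10) {
    A <- matrix(stats::rnorm(30, sd = 3), 10L)
    B <- A %*% random_rotation() + stats::rnorm(30, sd = 0.5)
    mine <- kabsch_superpose(B, A)$rmsd
    ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
    expect_equal(mine, ref, tolerance = 1e-3)  # bio3d rounds to 3 digits
    # optimal rmsd never exceeds the unaligned rmsd
    expect_lte(mine, sqrt(mean(rowSums((B - A)^2))) + 1e-12)
  }
})

test_that("rmsd_series reports displacement on the measured selection", {
  ref <- make_ca_frame(12, seed = 9)
  # trajectory of identical copies: all zeros
  traj <- trajectory(ref$atoms, list(ref$coords, ref$coords, ref$coords))
  expect_equal(rmsd_series(traj, ref, selection(resno = 1:12)), rep(0, 3),
               tolerance = 1e-12)
  # displace residues 9-12 by d after excluding them from the fit
  d <- 2.5
  moved <- ref$coords
  moved[9:12, 1] <- moved[9:12, 1] + d
  traj2 <- trajectory(ref$atoms, list(moved))
  out <- rmsd_series(traj2, ref, fit_selection = selection(resno = 1:8),
                     measure_selection = selection(resno = 9:12))
  expect_equal(out, d, tolerance = 1e-9)
})

test_that("rmsd histograms of a two-state synthetic trajectory are bimodal", {
  ref <- make_ca_frame(12, seed = 13)
  near <- ref$coords; near[, 1] <- near[, 1] + 0  # state A: identical
  far <- ref$coords
  far[7:12, 2] <- far[7:12, 2] + 4                # state B: shifted linker
  frames <- rep(list(near, far), 20)
  traj <- trajectory(ref$atoms, frames)
  # measure the shifted residues while fitting on the stable ones, so the
  # two constructed states map onto two RMSD levels
  r <- rmsd_series(traj, ref, fit_selection = selection(resno = 1:6),
                   measure_selection = selection(resno = 7:12))
  expect_equal(sort(unique(round(r, 6))), c(0, 4))
  expect_equal(mean(r < 2), 0.5)
})

test_that("rmsf matches closed forms and a naive two-pass recomputation", {
  ref <- make_ca_frame(8, seed = 21)
  # static trajectory: all zeros
  traj0 <- trajectory(ref$atoms, rep(list(ref$coords), 4))
  expect_true(all(rmsf(traj0)$rmsf < 1e-12))
  expect_error(rmsf(trajectory(ref$atoms, list(ref$coords))), "2 frames")

  # two-point alternation +-a of one atom: rmsf -> a as the static anchor
  # grows (superposition on few atoms redistributes part of the motion)
  big <- make_ca_frame(40, seed = 22)
  a <- 0.8
  upb <- big$coords; upb[4, 3] <- upb[4, 3] + a
  dnb <- big$coords; dnb[4, 3] <- dnb[4, 3] - a
  trajb <- trajectory(big$atoms, rep(list(upb, dnb), 10))
  gotb <- rmsf(trajb)$rmsf
  expect_equal(gotb[4], a, tolerance = 0.08)
  expect_true(all(gotb[-4] < 0.1))

  # small anchor: the moving atom still dominates, and the streaming value
  # equals a naive two-pass recomputation exactly
  up <- ref$coords; up[4, 3] <- up[4, 3] + a
  dn <- ref$coords; dn[4, 3] <- dn[4, 3] - a
  traj <- trajectory(ref$atoms, rep(list(up, dn), 10))
  got <- rmsf(traj)$rmsf
  expect_equal(which.max(got), 4L)
  # naive two-pass recomputation on the same aligned coordinates
  idx <- seq_len(8)
  coords <- lapply(traj$frames, function(fr) fr[idx, , drop = FALSE])
  aligned <- lapply(coords, function(x) {
    f <- kabsch_superpose(x, coords[[1]])
    sweep(x %*% f$rotation, 2, f$translation, `+`)
  })
  mstr <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(coords, function(x) {
    f <- kabsch_superpose(x, mstr)
    sweep(x %*% f$rotation, 2, f$translation, `+`)
  })
  mstr <- Reduce(`+`, aligned) / length(aligned)
  naive <- sqrt(Reduce(`+`, lapply(aligned, function(x)
    rowSums((x - mstr)^2))) / length(aligned))
  expect_equal(got, naive, tolerance = 1e-9)
})

test_that("state-plane endpoints sit at the reference distances", {
  a <- make_ca_frame(10, seed = 33)
  bcoords <- a$coords
  bcoords[, 1] <- bcoords[, 1] + 3  # pure translation: d(a,b)=0 after fit
  bcoords[6:10, 2] <- bcoords[6:10, 2] + 5
  b <- structure_frame(a$atoms, bcoords)
  sel <- selection(resno = 1:10)
  d_ab <- rmsd_series(trajectory(a$atoms, list(a$coords)), b, sel)
  traj_a <- trajectory(a$atoms, rep(list(a$coords), 3))
  sp <- state_plane(traj_a, a, b, sel)
  expect_equal(sp$rmsd_a, rep(0, 3), tolerance = 1e-12)
  expect_equal(sp$rmsd_b, rep(d_ab, 3), tolerance = 1e-9)
  # frames equal to b: mirrored
  traj_b <- trajectory(a$atoms, rep(list(bcoords), 2))
  sp2 <- state_plane(traj_b, a, b, sel)
  expect_equal(sp2$rmsd_b, rep(0, 2), tolerance = 1e-12)
  expect_equal(sp2$rmsd_a, rep(d_ab, 2), tolerance = 1e-9)
  # linear interpolation a -> b: monotone crossing of the plane
  lam <- seq(0, 1, length.out = 9)
  traj_i <- trajectory(a$atoms, lapply(lam, function(l)
    (1 - l) * a$coords + l * bcoords))
  spi <- state_plane(traj_i, a, b, sel)
  expect_true(all(diff(spi$rmsd_a) > -1e-9))
  expect_true(all(diff(spi$rmsd_b) < 1e-9))
})

test_that("torsion angles follow the IUPAC convention and a dual-formula oracle", {
  # trans (anti) four-atom chain: 180 degrees
  expect_equal(abs(torsion_angle(c(1, 0, 1), c(0, 0, 0), c(0, 0, -1),
                                 c(-1, 0, -2))), 180, tolerance = 1e-9)
  # eclipsed: 0 degrees
  expect_equal(torsion_angle(c(1, 0, 1), c(0, 0, 0), c(0, 0, -1),
                             c(1, 0, -2)), 0, tolerance = 1e-9)
  # constructed +60 gauche fixture
  fr <- make_gln_frame(60)
  expect_equal(unname(chi_dihedrals(fr, "A", 1)["chi1"]), 60,
               tolerance = 1e-6)
  # dual-formula oracle (projection construction) on random geometries
  oracle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    cx <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
            n1[1] * n2[2] - n1[2] * n2[1])
    atan2(sum(cx * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  }
  set.seed(91)
  for (rep in 1:200) {
    pts <- matrix(stats::rnorm(12), 4L)
    a1 <- torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    a2 <- oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    if (a2 <= -180) a2 <- a2 + 360
    expect_equal(a1, a2, tolerance = 1e-9)
  }
  # against bio3d's torsion implementation
  for (rep in 1:20) {
    pts <- matrix(stats::rnorm(12), 4L)
    a1 <- torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    a2 <- bio3d::torsion.xyz(as.numeric(t(pts)))
    expect_equal(a1, as.numeric(a2), tolerance = 1e-6)
  }
  # missing atom named in the error
  fr2 <- make_gln_frame(60)
  keep <- fr2$atoms$atom != "CD"
  fr2 <- structure_frame(fr2$atoms[keep, ], fr2$coords[keep, ])
  expect_error(chi_dihedrals(fr2, "A", 1), "CD")
})

test_that("atom distances and contact fractions are Euclidean", {
  atoms <- data.frame(chain = "A", resno = c(277L, 414L),
                      resname = c("GLN", "LEU"), atom = c("NE2", "O"),
                      element = c("N", "O"))
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  # coincident and 3-4-5 triangle
  tr <- trajectory(atoms, list(rbind(c(0, 0, 0), c(0, 0, 0)),
                               rbind(c(0, 0, 0), c(3, 4, 0))))
  out <- atom_distance_series(tr, list(chain = "A", resno = 277, atom = "NE2"),
                              list(chain = "A", resno = 414, atom = "O"))
  expect_equal(out$distance, c(0, 5))
  # alternating 3.0/4.0 A with cutoff 3.5: fraction one half
  tr2 <- trajectory(atoms, rep(list(mk(3), mk(4)), 10))
  out2 <- atom_distance_series(tr2,
                               list(chain = "A", resno = 277, atom = "NE2"),
                               list(chain = "A", resno = 414, atom = "O"))
  expect_equal(out2$fraction_within_cutoff, 0.5)
  expect_error(atom_distance_series(tr2,
                                    list(chain = "B", resno = 1, atom = "X"),
                                    list(chain = "A", resno = 414, atom = "O")),
               "resolves to 0")
})

test_that("all metrics are invariant under global rigid motion", {
  ref <- make_ca_frame(12, seed = 55)
  set.seed(56)
  frames <- lapply(1:6, function(k) ref$coords + matrix(stats::rnorm(36, sd = 0.3), 12L))
  traj <- trajectory(ref$atoms, frames)
  sel <- selection(resno = 1:12)
  base_rmsd <- rmsd_series(traj, ref, sel)
  base_rmsf <- rmsf(traj, sel)$rmsf
  R <- random_rotation(); tr <- c(10, -4, 2)
  moved <- lapply(frames, function(f) f %*% R + matrix(tr, 12L, 3L, byrow = TRUE))
  traj_m <- trajectory(ref$atoms, moved)
  expect_lt(max(abs(rmsd_series(traj_m, ref, sel) - base_rmsd)), 1e-9)
  expect_lt(max(abs(rmsf(traj_m, sel)$rmsf - base_rmsf)), 1e-9)
  # torsions too (internal coordinates)
  fr <- make_gln_frame(47)
  fr_m <- structure_frame(fr$atoms, fr$coords %*% R +
                            matrix(tr, nrow(fr$coords), 3L, byrow = TRUE))
  expect_lt(max(abs(chi_dihedrals(fr, "A", 1) - chi_dihedrals(fr_m, "A", 1))),
            1e-9)
})

test_that("multi-model PDB and coordinate-table trajectories load with stride", {
  fr <- make_ca_frame(6, seed = 99)
  # write a 4-model PDB by hand (bio3d writes single models)
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- character(0)
  for (m in 1:4) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    sh <- fr$coords + (m - 1) * 0.5
    for (i in 1:6) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, sh[i, 1], sh[i, 2], sh[i, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), p)
  traj <- read_trajectory(p)
  expect_length(traj$frames, 4L)
  expect_equal(traj$frames[[2]] - traj$frames[[1]],
               matrix(0.5, 6L, 3L), tolerance = 1e-6)
  # stride 2 keeps frames 1 and 3
  traj2 <- read_trajectory(p, stride = 2L)
  expect_length(traj2$frames, 2L)
  # coordinate-table dialect against a topology PDB
  top <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_frame(fr, top)
  tab <- withr::local_tempfile(fileext = ".dat")
  rows <- c()
  for (m in 1:3) for (i in 1:6) {
    rows <- c(rows, sprintf("%d %d %.3f %.3f %.3f", m, i,
                            fr$coords[i, 1] + m, fr$coords[i, 2],
                            fr$coords[i, 3]))
  }
  writeLines(rows, tab)
  traj3 <- read_trajectory(tab, topology = top)
  expect_length(traj3$frames, 3L)
  expect_equal(traj3$frames[[3]][, 1] - traj3$frames[[1]][, 1], rep(2, 6L),
               tolerance = 1e-6)
})
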