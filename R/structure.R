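#' Read a PDB structure frame
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d) into a structure
#' frame: an atom table (chain, residue number, residue name, atom name,
#' element, insertion code) plus an N x 3 coordinate matrix in Angstrom.
#' When alternate locations are present, the highest-occupancy altloc is
#' kept per atom; insertion codes are preserved in the residue key.
#'
#' @param path PDB file path.
#' @param model model number for multi-model files (default 1).
#' @return a `structure_frame`.
#' @export
read_pdb_frame <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse PDB '", path, "': ",
                         conditionMessage(e))
                  })
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  n_models <- nrow(pdb$xyz)
  if (model > n_models) stop("model ", model, " not present (file has ",
                             n_models, ")")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  frame <- structure_frame(
    data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
               atom = at$elety, element = at$elesy, insert = at$insert,
               stringsAsFactors = FALSE),
    xyz)
  drop_altloc(frame, at$alt, at$o)
}

# keep the highest-occupancy altloc per (chain, resno, insert, atom)
drop_altloc <- function(frame, alt, occ) {
  alt[is.na(alt)] <- ""
  occ[is.na(occ)] <- 1
  if (all(alt == "")) return(frame)
  key <- paste(frame$atoms$chain, frame$atoms$resno, frame$atoms$insert,
               frame$atoms$atom, sep = "|")
  keep <- unlist(lapply(split(seq_along(key), key), function(ii) {
    ii[which.max(occ[ii])]
  }), use.names = FALSE)
  keep <- sort(keep)
  structure_frame(frame$atoms[keep, , drop = FALSE],
                  frame$coords[keep, , drop = FALSE])
}

#' Construct a structure frame
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element` (and optionally `insert`); (chain, resno, insert,
#'   atom) must be unique.
#' @param coords numeric N x 3 matrix (Angstrom).
#' @return a `structure_frame`.
#' @export
structure_frame <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms), is.matrix(coords), ncol(coords) == 3L,
            nrow(atoms) == nrow(coords))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) keys: ",
         key[duplicated(key)][1L])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, coords = unname(coords)),
            class = "structure_frame")
}

#' Write a structure frame as PDB
#'
#' @param frame a `structure_frame`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pdb_frame <- function(frame, path) {
  stopifnot(inherits(frame, "structure_frame"))
  a <- frame$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(frame$coords)),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   elety = a$atom, elesy = a$element)
  invisible(path)
}

#' A coordinate trajectory over a shared atom table
#'
#' @param atoms shared atom table (as in [structure_frame()]).
#' @param frames list of N x 3 coordinate matrices, congruent in atom
#'   ordering.
#' @param frame_interval time between frames (ns).
#' @return a `trajectory`.
#' @export
trajectory <- function(atoms, frames, frame_interval = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- nrow(atoms)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L) {
      stop("all frames must be N x 3 matrices congruent with the atom table")
    }
  }
  f0 <- structure_frame(atoms, frames[[1L]])  # validates the atom table
  structure(list(atoms = f0$atoms, frames = lapply(frames, unname),
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' Read a trajectory
#'
#' Two formats: a multi-model PDB (each MODEL a frame), or a plain
#' whitespace-separated coordinate table with columns
#' `frame atom_index x y z` paired with a reference PDB that supplies the
#' atom table. Native MD binary formats are out of scope; convert upstream.
#'
#' @param path multi-model PDB, or coordinate table when `topology` given.
#' @param topology PDB path supplying the atom table for table input.
#' @param frame_interval time between frames (ns).
#' @param stride keep every `stride`-th frame (default 1).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL, frame_interval = 1,
                            stride = 1L) {
  stopifnot(stride >= 1L)
  if (is.null(topology)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    ref <- read_pdb_frame(path, model = 1L)
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(m) {
      matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    })
  } else {
    ref <- read_pdb_frame(topology)
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("frame", "atom", "x", "y", "z"))
    frames <- lapply(split(tab, tab$frame), function(d) {
      d <- d[order(d$atom), ]
      if (nrow(d) != nrow(ref$atoms)) {
        stop("frame ", d$frame[1L], " has ", nrow(d), " atoms; topology has ",
             nrow(ref$atoms))
      }
      as.matrix(d[, c("x", "y", "z")])
    })
  }
  frames <- frames[seq(1L, length(frames), by = stride)]
  trajectory(ref$atoms, frames, frame_interval * stride)
}

#' Atom selection
#'
#' @param chain chain id(s), or NULL for all.
#' @param resno residue numbers (e.g. `409:420`), or NULL for all.
#' @param atom atom name(s) (e.g. `"CA"`), or NULL for all.
#' @return a `selection` object.
#' @export
selection <- function(chain = NULL, resno = NULL, atom = "CA") {
  structure(list(chain = chain, resno = resno, atom = atom),
            class = "selection")
}

resolve_selection <- function(atoms, sel) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & atoms$resno %in% sel$resno
  if (!is.null(sel$atom)) keep <- keep & atoms$atom %in% sel$atom
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection resolves to no atoms")
  idx
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` by
#' singular value decomposition of the covariance matrix, with the
#' reflection branch excluded (proper rotations only).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3,
#'   non-collinear.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `coords %*% rotation + translation`), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(reference, 2L, cr)
  # collinearity check: centered point set must span >= 2 dimensions
  if (sum(svd(A)$d > 1e-9 * max(1, max(abs(A)))) < 2L) {
    stop("degenerate (collinear) atom set; superposition is ill-posed")
  }
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- A %*% R
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, `+`)
}

#' RMSD time series against a reference
#'
#' Per frame: superpose on `fit_selection`, then report the RMSD over
#' `measure_selection`. With the defaults the two selections coincide — the
#' local alignment used for the linker analyses (superpose on the linker
#' C-alphas, measure the same atoms). Distinct selections give
#' global-then-local alignment.
#'
#' @param traj a `trajectory`.
#' @param reference a `structure_frame`.
#' @param fit_selection a `selection` used for superposition.
#' @param measure_selection a `selection` measured after superposition
#'   (default: same as `fit_selection`).
#' @return numeric RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference, fit_selection,
                        measure_selection = fit_selection) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(reference, "structure_frame"))
  fit_t <- resolve_selection(traj$atoms, fit_selection)
  fit_r <- resolve_selection(reference$atoms, fit_selection)
  mea_t <- resolve_selection(traj$atoms, measure_selection)
  mea_r <- resolve_selection(reference$atoms, measure_selection)
  if (length(fit_t) != length(fit_r) || length(mea_t) != length(mea_r)) {
    stop("selection resolves to different atom counts on trajectory and reference")
  }
  ref_fit <- reference$coords[fit_r, , drop = FALSE]
  ref_mea <- reference$coords[mea_r, , drop = FALSE]
  vapply(traj$frames, function(fr) {
    fit <- kabsch_superpose(fr[fit_t, , drop = FALSE], ref_fit)
    moved <- apply_transform(fr[mea_t, , drop = FALSE], fit)
    sqrt(mean(rowSums((moved - ref_mea)^2)))
  }, numeric(1))
}

#' Root-mean-square fluctuation per residue
#'
#' Frames are superposed on the selection (first onto the first frame, then
#' onto the resulting mean structure), and each selected atom's RMSF is the
#' square root of its mean squared deviation from its time-averaged
#' position. With a C-alpha selection the per-atom values are the
#' per-residue values.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param sel a `selection` (default C-alpha atoms).
#' @return data.frame with `chain`, `resno`, `atom`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, sel = selection()) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L) stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(traj$atoms, sel)
  coords <- lapply(traj$frames, function(fr) fr[idx, , drop = FALSE])
  ref <- coords[[1L]]
  aligned <- lapply(coords, function(x) {
    apply_transform(x, kabsch_superpose(x, ref))
  })
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(coords, function(x) {
    apply_transform(x, kabsch_superpose(x, mean_str))
  })
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  sq <- Reduce(`+`, lapply(aligned, function(x) rowSums((x - mean_str)^2)))
  data.frame(chain = traj$atoms$chain[idx], resno = traj$atoms$resno[idx],
             atom = traj$atoms$atom[idx],
             rmsf = sqrt(sq / length(aligned)))
}

#' Two-reference RMSD state plane
#'
#' RMSD of each frame to two reference structures (e.g. resting and
#' desensitized states) under the same superposition rules, for plotting
#' conformational trajectories in the plane spanned by the two states.
#'
#' @param traj a `trajectory`.
#' @param reference_a,reference_b `structure_frame` references.
#' @param sel a `selection`.
#' @return data.frame with `time` (ns), `rmsd_a`, `rmsd_b` per frame.
#' @export
state_plane <- function(traj, reference_a, reference_b, sel) {
  data.frame(
    time = (seq_along(traj$frames) - 1L) * traj$frame_interval,
    rmsd_a = rmsd_series(traj, reference_a, sel),
    rmsd_b = rmsd_series(traj, reference_b, sel))
}

# chi dihedral atom quadruples by residue type (chi1..chi3 where defined)
chi_atom_table <- list(
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  VAL = list(c("N", "CA", "CB", "CG1")))

#' Signed torsion angle of four points
#'
#' Standard four-atom construction with the IUPAC sign convention: the
#' angle between the plane (p1,p2,p3) and the plane (p2,p3,p4), positive
#' for a clockwise rotation of p4 relative to p1 looking down p2 -> p3;
#' result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return torsion angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Side-chain chi dihedrals of one residue
#'
#' @param frame a `structure_frame`.
#' @param chain chain id.
#' @param resno residue number.
#' @return named numeric vector (`chi1`, `chi2`, `chi3` as defined for the
#'   residue type), degrees in (-180, 180].
#' @export
chi_dihedrals <- function(frame, chain, resno) {
  stopifnot(inherits(frame, "structure_frame"))
  sel <- frame$atoms$chain == chain & frame$atoms$resno == resno
  if (!any(sel)) stop("residue ", chain, ":", resno, " not found")
  resname <- frame$atoms$resname[sel][1L]
  quads <- chi_atom_table[[toupper(resname)]]
  if (is.null(quads)) stop("no chi dihedrals defined for residue type ",
                           resname)
  get_xyz <- function(atom) {
    j <- which(sel & frame$atoms$atom == atom)
    if (length(j) == 0L) {
      stop(sprintf("missing atom %s in %s %s:%d", atom, resname, chain,
                   resno))
    }
    frame$coords[j[1L], ]
  }
  out <- vapply(quads, function(q) {
    torsion_angle(get_xyz(q[1L]), get_xyz(q[2L]), get_xyz(q[3L]),
                  get_xyz(q[4L]))
  }, numeric(1))
  names(out) <- paste0("chi", seq_along(out))
  out
}

#' Atom-pair distance series
#'
#' Euclidean distance between two named atoms across all frames, with an
#' optional hydrogen-bond-style threshold report.
#'
#' @param traj a `trajectory`.
#' @param atom_a,atom_b lists `list(chain=, resno=, atom=)`.
#' @param cutoff distance cutoff (Angstrom) for the contact fraction
#'   (default 3.5).
#' @return list with `distance` (Angstrom per frame) and
#'   `fraction_within_cutoff`.
#' @export
atom_distance_series <- function(traj, atom_a, atom_b, cutoff = 3.5) {
  stopifnot(inherits(traj, "trajectory"))
  find1 <- function(a, what) {
    j <- which(traj$atoms$chain == a$chain & traj$atoms$resno == a$resno &
                 traj$atoms$atom == a$atom)
    if (length(j) != 1L) {
      stop(sprintf("atom %s %s:%s resolves to %d atoms", what,
                   a$chain, a$atom, length(j)))
    }
    j
  }
  ia <- find1(atom_a, "a"); ib <- find1(atom_b, "b")
  d <- vapply(traj$frames, function(fr) {
    sqrt(sum((fr[ia, ] - fr[ib, ])^2))
  }, numeric(1))
  list(distance = d, fraction_within_cutoff = mean(d <= cutoff))
}
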