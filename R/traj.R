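# Trajectory statistics: Kabsch superposition and RMSD series, geometric
# hydrogen-bond contact populations, backbone phi/psi dihedral series,
# zinc-coordination checks, and a synthetic-trajectory generator used to
# validate all of the above by construction.
#
# A trajectory holds an atom table (name, resname, resid, chain) and a
# frames x atoms x 3 coordinate array in Angstrom.

#' Construct a trajectory
#'
#' @param atoms A tibble with columns `name`, `resname`, `resid`, `chain`.
#' @param coords Numeric array `[n_frames, n_atoms, 3]` in Angstrom, or a
#'   single `n_atoms x 3` matrix (one frame).
#' @param time Optional per-frame times (ps).
#' @return A `trajectory` object.
#' @export
trajectory <- function(atoms, coords, time = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, nrow(coords), 3))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(atoms))
    abort("coords atom dimension does not match the atom table")
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  req <- c("name", "resname", "resid", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  structure(list(atoms = as_tibble(atoms), coords = coords, time = time),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", dim(x$coords)[1], "frames,", dim(x$coords)[2], "atoms\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Resolve an atom selection
#'
#' Selections use the mini-language `"chain:resid:atom"` with `*` as a
#' wildcard in any field (e.g. `"A:6:N"`, `"*:*:CA"`), or may be given
#' directly as integer atom indices.
#'
#' @param traj A [trajectory()].
#' @param sel Character vector of selector strings, or integer indices.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(traj, sel) {
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (any(sel < 1 | sel > nrow(traj$atoms))) abort("atom index out of range")
    return(sel)
  }
  out <- integer(0)
  for (s in sel) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      abort(paste0("selector '", s, "' is not 'chain:resid:atom'"))
    keep <- rep(TRUE, nrow(traj$atoms))
    if (parts[1] != "*") keep <- keep & traj$atoms$chain == parts[1]
    if (parts[2] != "*") keep <- keep & traj$atoms$resid == as.integer(parts[2])
    if (parts[3] != "*") keep <- keep & traj$atoms$name == parts[3]
    hit <- which(keep)
    if (!length(hit)) abort(paste0("selector '", s, "' matches no atom"))
    out <- c(out, hit)
  }
  unique(out)
}

# resolve a selector that must name exactly one atom
select_one <- function(traj, sel) {
  idx <- select_atoms(traj, sel)
  if (length(idx) != 1)
    abort(paste0("selector '", paste(sel, collapse = ","),
                 "' must resolve to exactly one atom"))
  idx
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of a mobile coordinate set onto a reference
#' by SVD of the covariance matrix, restricted to proper rotations
#' (reflections are corrected by sign flip of the smallest singular vector).
#'
#' @param ref,mobile `n x 3` coordinate matrices over the same atoms.
#' @param selection Optional integer indices of the rows used for the fit
#'   (default all); at least 3 non-collinear atoms.
#' @return A list with `rotation` (3x3, applied as `x %*% t(rotation)`),
#'   `translation`, `rmsd` (over the selection after superposition), and
#'   `transform(x)` applying the fit to arbitrary coordinates.
#' @export
superpose_kabsch <- function(ref, mobile, selection = NULL) {
  selection <- selection %||% seq_len(nrow(ref))
  P <- mobile[selection, , drop = FALSE]
  Q <- ref[selection, , drop = FALSE]
  if (nrow(P) < 3) abort("need at least 3 atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-8 * max(svd(Pc)$d[1], 1))
    abort("selection is collinear; superposition is degenerate")
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  list(rotation = R, translation = cq, center = cp, rmsd = rmsd,
       transform = function(x) sweep(sweep(x, 2, cp) %*% t(R), 2, cq, `+`))
}

#' Per-frame RMSD relative to the first frame
#'
#' Each frame is superposed onto frame 1 on the selection with
#' [superpose_kabsch()]; the RMSD over the selection after superposition is
#' reported.
#'
#' @param traj A [trajectory()].
#' @param selection Selector strings or indices (default: all atoms).
#' @return A tibble with columns `frame` (1-based) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection = NULL) {
  nf <- n_frames(traj)
  if (nf == 0) return(tibble(frame = integer(), rmsd = numeric()))
  idx <- if (is.null(selection)) seq_len(nrow(traj$atoms))
         else select_atoms(traj, selection)
  ref <- traj$coords[1, , ]
  rmsd <- map_dbl(seq_len(nf), function(f) {
    if (f == 1) return(0)
    superpose_kabsch(ref, traj$coords[f, , ], selection = idx)$rmsd
  })
  tibble(frame = seq_len(nf), rmsd = rmsd)
}

#' Hydrogen-bond specification
#'
#' Geometric criterion: a frame satisfies the contact iff the donor-acceptor
#' distance is `<= distance_cutoff` and the hydrogen-donor-acceptor angle is
#' `<= angle_cutoff`; boundary values count as satisfied.
#'
#' @param donor,hydrogen,acceptor Selectors resolving to exactly one atom
#'   each (see [select_atoms()]).
#' @param distance_cutoff Donor-acceptor distance cutoff in Angstrom.
#' @param angle_cutoff Hydrogen-donor-acceptor angle cutoff in degrees.
#' @param label Optional display name.
#' @return A one-row tibble usable in [hbond_populations()].
#' @export
hbond_spec <- function(donor, hydrogen, acceptor,
                       distance_cutoff = acecleave_defaults()$hbond_dist,
                       angle_cutoff = acecleave_defaults()$hbond_angle,
                       label = NULL) {
  if (distance_cutoff <= 0 || angle_cutoff <= 0) abort("cutoffs must be positive")
  tibble(label = label %||% paste0(donor, " -> ", acceptor),
         donor = donor, hydrogen = hydrogen, acceptor = acceptor,
         distance_cutoff = distance_cutoff, angle_cutoff = angle_cutoff)
}

#' Hydrogen-bond contact populations
#'
#' @param traj A [trajectory()].
#' @param specs A tibble of [hbond_spec()] rows.
#' @return A tibble with the spec columns plus `n_frames`, `n_satisfied`,
#'   `population` (fraction of frames in `[0, 1]`).
#' @export
hbond_populations <- function(traj, specs) {
  nf <- n_frames(traj)
  rows <- map(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    d_i <- select_one(traj, sp$donor)
    h_i <- select_one(traj, sp$hydrogen)
    a_i <- select_one(traj, sp$acceptor)
    ok <- map_lgl(seq_len(nf), function(f) {
      D <- traj$coords[f, d_i, ]; H <- traj$coords[f, h_i, ]
      A <- traj$coords[f, a_i, ]
      dist <- sqrt(sum((A - D)^2))
      if (dist > sp$distance_cutoff) return(FALSE)
      v1 <- H - D; v2 <- A - D
      ang <- angle_deg(v1, v2)
      ang <= sp$angle_cutoff
    })
    mutate(sp, n_frames = nf, n_satisfied = sum(ok),
           population = sum(ok) / nf)
  })
  bind_rows(rows)
}

angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed dihedral over four points, IUPAC convention, degrees in (-180, 180]
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  if (identical(ang, -180)) ang <- 180
  ang
}

#' Backbone dihedral time series
#'
#' phi(i) is the C(i-1)-N(i)-CA(i)-C(i) dihedral, psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) dihedral, signed per the IUPAC convention in
#' `(-180, 180]` degrees.
#'
#' @param traj A [trajectory()].
#' @param resid Residue index.
#' @param angle `"phi"` or `"psi"`.
#' @param chain Chain identifier (`"*"` for any).
#' @return A tibble with columns `frame`, `angle` (degrees).
#' @export
dihedral_series <- function(traj, resid, angle = c("psi", "phi"), chain = "*") {
  angle <- match.arg(angle)
  sel <- function(r, nm) select_one(traj, paste(chain, r, nm, sep = ":"))
  idx <- if (angle == "phi") {
    c(sel(resid - 1, "C"), sel(resid, "N"), sel(resid, "CA"), sel(resid, "C"))
  } else {
    c(sel(resid, "N"), sel(resid, "CA"), sel(resid, "C"), sel(resid + 1, "N"))
  }
  vals <- map_dbl(seq_len(n_frames(traj)), function(f) {
    x <- traj$coords[f, idx, ]
    dihedral_deg(x[1, ], x[2, ], x[3, ], x[4, ])
  })
  tibble(frame = seq_len(n_frames(traj)), angle = vals)
}

#' Circular mean and variance of angles in degrees
#'
#' @param deg Numeric vector of angles in degrees.
#' @return A list with `mean` (degrees in `(-180, 180]`) and `var`
#'   (`1 - mean resultant length`, in `[0, 1]`).
#' @export
circular_stats <- function(deg) {
  rad <- deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  list(mean = atan2(s, c) * 180 / pi, var = 1 - sqrt(s^2 + c^2))
}

#' Tetrahedral zinc-coordination check
#'
#' For each frame, reports the four zinc-ligand distances and the mean
#' absolute deviation of the six ligand-Zn-ligand angles from the ideal
#' tetrahedral angle (109.47 deg). Coordination is `retained` iff all
#' distances fall within `dist_range` and the mean angle deviation is at
#' most `angle_tol`.
#'
#' @param traj A [trajectory()].
#' @param zinc Selector for the zinc atom.
#' @param ligands Character vector of exactly four ligand-atom selectors.
#' @param dist_range Allowed Zn-ligand distance range (Angstrom).
#' @param angle_tol Allowed mean angle deviation (degrees).
#' @return A tibble with `frame`, `d1`-`d4`, `angle_dev`, `retained`.
#' @export
zinc_geometry_check <- function(traj, zinc, ligands,
                                dist_range = c(1.8, 2.6), angle_tol = 15) {
  if (length(ligands) != 4) abort("exactly 4 ligand selectors required")
  z_i <- select_one(traj, zinc)
  l_i <- map_dbl(ligands, ~ select_one(traj, .x))
  pairs <- utils::combn(4, 2)
  rows <- map(seq_len(n_frames(traj)), function(f) {
    z <- traj$coords[f, z_i, ]
    L <- traj$coords[f, l_i, , drop = TRUE]
    d <- sqrt(rowSums(sweep(L, 2, z)^2))
    angs <- map_dbl(seq_len(ncol(pairs)), function(p) {
      angle_deg(L[pairs[1, p], ] - z, L[pairs[2, p], ] - z)
    })
    dev <- mean(abs(angs - 109.47))
    tibble(frame = f, d1 = d[1], d2 = d[2], d3 = d[3], d4 = d[4],
           angle_dev = dev,
           retained = all(d >= dist_range[1] & d <= dist_range[2]) &&
             dev <= angle_tol)
  })
  bind_rows(rows)
}

#' Generate a synthetic trajectory with scheduled contacts
#'
#' Replicates a template frame, geometrically enforcing each scheduled
#' hydrogen-bond contact per frame -- the acceptor atom is placed on the
#' donor-hydrogen axis at 2.9 Angstrom when the contact is "on" and at
#' 6 Angstrom when "off" -- then adds isotropic Gaussian jitter. With a fixed
#' seed the output is bit-reproducible. This is the fixture generator used to
#' validate the contact-population and RMSD machinery by construction.
#'
#' @param template A [trajectory()] (frame 1 is the template) or an
#'   `n_atoms x 3` matrix with an atom table attached via [trajectory()].
#' @param n_frames Number of frames to generate.
#' @param schedule Optional list of `list(spec = hbond_spec row, on = logical
#'   vector of length n_frames)`.
#' @param jitter SD (Angstrom) of the Gaussian coordinate noise.
#' @param seed Optional RNG seed.
#' @return A [trajectory()].
#' @export
synth_trajectory <- function(template, n_frames, schedule = NULL,
                             jitter = 0, seed = NULL) {
  stopifnot(inherits(template, "trajectory"))
  base <- template$coords[1, , ]
  na <- nrow(template$atoms)
  with_seed(seed, {
    coords <- array(0, dim = c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      x <- base
      for (sch in schedule) {
        sp <- sch$spec
        d_i <- select_one(template, sp$donor)
        h_i <- select_one(template, sp$hydrogen)
        a_i <- select_one(template, sp$acceptor)
        u <- x[h_i, ] - x[d_i, ]
        u <- u / sqrt(sum(u^2))
        dist <- if (sch$on[f]) 2.9 else 6.0
        x[a_i, ] <- x[d_i, ] + dist * u
      }
      if (jitter > 0) x <- x + rnorm(length(x), 0, jitter)
      coords[f, , ] <- x
    }
    trajectory(template$atoms, coords)
  })
}

#' Read a multi-model PDB file as a trajectory
#'
#' Uses `bio3d::read.pdb()`; each MODEL becomes one frame.
#'
#' @param path Path to a PDB file.
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort("read_pdb_trajectory() requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  atoms <- tibble(
    name = pdb$atom$elety, resname = pdb$atom$resid,
    resid = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain)
  )
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, nrow(atoms), 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(atoms, coords)
}

#' Read an XYZ trajectory
#'
#' Plain multi-frame XYZ (atom count line, comment line, then
#' `name x y z` rows). Atom names become both `name` and `resname`; residue
#' index and chain default to the atom order and `"A"` since XYZ carries no
#' topology.
#'
#' @param path Path to an .xyz file.
#' @param units `"angstrom"` (default) or `"nm"`; nm coordinates are
#'   converted to Angstrom.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines))]
  frames <- list(); i <- 1
  while (i <= length(lines)) {
    na <- as.integer(str_trim(lines[i]))
    block <- lines[(i + 2):(i + 1 + na)]
    toks <- do.call(rbind, str_split(str_trim(block), "[[:space:]]+"))
    frames <- c(frames, list(list(
      names = toks[, 1],
      xyz = matrix(as.numeric(toks[, 2:4]), ncol = 3)
    )))
    i <- i + 2 + na
  }
  atoms <- tibble(name = frames[[1]]$names, resname = frames[[1]]$names,
                  resid = seq_along(frames[[1]]$names), chain = "A")
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]$xyz
  if (units == "nm") coords <- coords * 10
  trajectory(atoms, coords)
}

#' Write a result table as TSV
#'
#' Plain tab-separated writer for RMSD/dihedral series and contact-population
#' tables.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
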