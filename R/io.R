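# File formats: extended XYZ (default trajectory interchange), PDB, LAMMPS
# data ("full" atom style), Gaussian cube for SDF grids, YAML run configs.

#' Write / read an extended-XYZ trajectory
#'
#' Plain XYZ with the comment line carrying `time=<fs> box=<Angstrom>`;
#' coordinates are written with 0.001 Angstrom precision and round-trip
#' losslessly at that precision.
#'
#' @param traj a `bilff_trajectory` (or anything with `frames`, `time`,
#'   `box` and a topology carrying elements).
#' @param path file path.
#' @param frames frame indices (default all).
#' @return `write_xyz`: the path, invisibly. `read_xyz`: a
#'   `bilff_trajectory` with a bare topology (elements only).
#' @export
write_xyz <- function(traj, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  el <- traj$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    p <- frame_pos(traj, f)
    writeLines(as.character(length(el)), con)
    writeLines(sprintf("time=%.3f box=%.6f", traj$time[f], .traj_box(traj, f)), con)
    writeLines(sprintf("%-2s %12.3f %12.3f %12.3f", el, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1; nline <- length(lines)
  frames <- list(); times <- numeric(); boxes <- numeric(); el <- NULL
  while (i <= nline) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1 + n > nline) stop("XYZ parse error at line ", i,
                                ": truncated frame (expected ", n, " atoms)")
    comment <- lines[i + 1]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    bx <- regmatches(comment, regexec("box=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else length(times) * 1.0)
    boxes <- c(boxes, if (length(bx) == 2) as.numeric(bx[2]) else 0)
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "[[:space:]]+")
    bad <- which(lengths(rows) < 4)
    if (length(bad)) stop("XYZ parse error at line ", i + 1 + bad[1],
                          ": expected 'element x y z'")
    elf <- vapply(rows, `[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("XYZ parse error in frame at line ", i,
                         ": non-numeric coordinate")
    if (is.null(el)) el <- elf
    else if (length(elf) != length(el)) stop("XYZ frames have differing atom counts")
    frames[[length(frames) + 1]] <- as.vector(t(xyz))
    i <- i + 2 + n
  }
  if (!length(frames)) {
    sys <- raw_system(matrix(numeric(0), 0, 3), box = 0)
    return(.as_traj(sys, matrix(numeric(0), 0, 0), 1, 0))
  }
  fm <- do.call(rbind, frames)
  sys <- raw_system(matrix(fm[1, ], ncol = 3, byrow = TRUE), box = boxes[1])
  sys$atoms$element <- el
  tr <- .as_traj(sys, fm, 1, boxes[1])
  tr$time <- times
  tr$box <- boxes
  tr
}

#' Write / read a single frame as PDB
#'
#' Writes CRYST1 (cubic box) and ATOM records; reading uses the bio3d
#' parser and returns positions, elements and the box edge.
#'
#' @param traj a `bilff_trajectory`.
#' @param path file path.
#' @param frame frame index.
#' @return `write_pdb`: the path, invisibly. `read_pdb_frame`: list with
#'   `pos` (N x 3, Angstrom), `element`, `box` (Angstrom).
#' @export
write_pdb <- function(traj, path, frame = n_frames(traj)) {
  p <- frame_pos(traj, frame)
  a <- traj$topology$atoms
  L <- .traj_box(traj, frame)
  con <- file(path, "w")
  on.exit(close(con))
  if (L > 0)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       L, L, L, 90, 90, 90), con)
  # wrap long labels into the 4-char atom-name field
  nm <- substr(a$label, 1, 4)
  writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(p)) %% 100000, nm,
                     substr(a$species, 1, 3), a$mol_id %% 10000,
                     p[, 1], p[, 2], p[, 3], 1, 0,
                     ifelse(a$element == "M", "X", a$element)), con)
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_pdb
#' @export
read_pdb_frame <- function(path) {
  pdb <- bio3d::read.pdb(path)
  pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  box <- 0
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr)) box <- as.numeric(substr(cr[1], 7, 15))
  list(pos = pos, element = trimws(pdb$atom$elesy), box = box)
}

#' Write a LAMMPS data file ("full" atom style)
#'
#' Emits masses, per-type pair coefficients (epsilon, sigma), bond, angle
#' and dihedral coefficients and term lists, and the scaled charges, for a
#' fully parameterized system. Units are kJ/mol and Angstrom as used
#' throughout the package. [read_lammps_data()] is the bundled reader; a
#' write/read round trip reproduces charges and coordinates exactly at the
#' written precision.
#'
#' @param sys a `bilff_system` with positions.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_lammps_data <- function(sys, path) {
  stopifnot(!is.null(sys$pos))
  a <- sys$atoms
  tkey <- paste(a$species, a$type)
  types <- unique(tkey)
  tid <- match(tkey, types)
  bkey <- paste(sys$bonds$l0, sys$bonds$kl)
  btypes <- unique(bkey); btid <- match(bkey, btypes)
  akey <- paste(sys$angles$theta0, sys$angles$ktheta)
  atypes <- unique(akey); atid <- match(akey, atypes)
  dkey <- paste(sys$dihedrals$V1, sys$dihedrals$V2, sys$dihedrals$V3,
                sys$dihedrals$V4)
  dtypes <- unique(dkey); dtid <- match(dkey, dtypes)

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file generated by bilff (units: kJ/mol, Angstrom)")
  w("")
  w("%d atoms", nrow(a))
  w("%d bonds", nrow(sys$bonds))
  w("%d angles", nrow(sys$angles))
  w("%d dihedrals", nrow(sys$dihedrals))
  w("%d atom types", length(types))
  if (length(btypes)) w("%d bond types", length(btypes))
  if (length(atypes)) w("%d angle types", length(atypes))
  if (length(dtypes)) w("%d dihedral types", length(dtypes))
  w("")
  L <- if (sys$box > 0) sys$box else max(abs(sys$pos)) + 10
  w("0.0 %.10g xlo xhi", L); w("0.0 %.10g ylo yhi", L); w("0.0 %.10g zlo zhi", L)
  w(""); w("Masses"); w("")
  first <- match(types, tkey)
  for (t in seq_along(types)) w("%d %.10g  # %s", t, a$mass[first[t]], types[t])
  w(""); w("Pair Coeffs  # epsilon sigma"); w("")
  for (t in seq_along(types)) w("%d %.10g %.10g", t, a$epsilon[first[t]],
                                a$sigma[first[t]])
  if (length(btypes)) {
    w(""); w("Bond Coeffs  # kl l0"); w("")
    fb <- match(btypes, bkey)
    for (t in seq_along(btypes)) w("%d %.10g %.10g", t, sys$bonds$kl[fb[t]],
                                   sys$bonds$l0[fb[t]])
  }
  if (length(atypes)) {
    w(""); w("Angle Coeffs  # ktheta theta0"); w("")
    fa <- match(atypes, akey)
    for (t in seq_along(atypes)) w("%d %.10g %.10g", t, sys$angles$ktheta[fa[t]],
                                   sys$angles$theta0[fa[t]])
  }
  if (length(dtypes)) {
    w(""); w("Dihedral Coeffs  # V1 V2 V3 V4"); w("")
    fd <- match(dtypes, dkey)
    for (t in seq_along(dtypes)) w("%d %.10g %.10g %.10g %.10g", t,
                                   sys$dihedrals$V1[fd[t]], sys$dihedrals$V2[fd[t]],
                                   sys$dihedrals$V3[fd[t]], sys$dihedrals$V4[fd[t]])
  }
  w(""); w("Atoms  # full: id mol type q x y z"); w("")
  for (i in seq_len(nrow(a)))
    w("%d %d %d %.10g %.10g %.10g %.10g", i, a$mol_id[i], tid[i], a$q[i],
      sys$pos[i, 1], sys$pos[i, 2], sys$pos[i, 3])
  if (nrow(sys$bonds)) {
    w(""); w("Bonds"); w("")
    for (r in seq_len(nrow(sys$bonds)))
      w("%d %d %d %d", r, btid[r], sys$bonds$i[r], sys$bonds$j[r])
  }
  if (nrow(sys$angles)) {
    w(""); w("Angles"); w("")
    for (r in seq_len(nrow(sys$angles)))
      w("%d %d %d %d %d", r, atid[r], sys$angles$i[r], sys$angles$j[r],
        sys$angles$k[r])
  }
  if (nrow(sys$dihedrals)) {
    w(""); w("Dihedrals"); w("")
    for (r in seq_len(nrow(sys$dihedrals)))
      w("%d %d %d %d %d %d", r, dtid[r], sys$dihedrals$i[r], sys$dihedrals$j[r],
        sys$dihedrals$k[r], sys$dihedrals$l[r])
  }
  invisible(path)
}

#' Read a LAMMPS data file written by [write_lammps_data()]
#'
#' @param path file path.
#' @return a `bilff_system` (generic atom labels; exclusion map not
#'   reconstructed).
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  get_count <- function(what) {
    m <- grep(paste0("^\\s*\\d+\\s+", what, "\\s*$"), lines, value = TRUE)
    if (!length(m)) 0L else as.integer(strsplit(trimws(m[1]), "\\s+")[[1]][1])
  }
  n <- get_count("atoms")
  section <- function(name, ncols, nrows) {
    i <- grep(paste0("^\\s*", name, "\\s*$"), lines)
    if (!length(i) || nrows == 0) return(NULL)
    block <- lines[(i[1] + 1):length(lines)]
    block <- block[nzchar(trimws(block))][seq_len(nrows)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                               function(r) as.numeric(r[seq_len(ncols)])))
    m
  }
  xhi <- as.numeric(strsplit(trimws(grep("xlo xhi", lines, value = TRUE)[1]),
                             "\\s+")[[1]][2])
  nt <- get_count("atom types")
  mass <- section("Masses", 2, nt)
  pair <- section("Pair Coeffs", 3, nt)
  atoms <- section("Atoms", 7, n)
  atoms <- atoms[order(atoms[, 1]), , drop = FALSE]
  tid <- atoms[, 3]
  sysr <- raw_system(atoms[, 5:7, drop = FALSE], box = xhi,
                     q = atoms[, 4], sigma = pair[tid, 3],
                     epsilon = pair[tid, 2], mass = mass[tid, 2],
                     mol_id = as.integer(atoms[, 2]))
  nb <- get_count("bonds"); na_ <- get_count("angles"); nd <- get_count("dihedrals")
  bc <- section("Bond Coeffs", 3, get_count("bond types"))
  ac <- section("Angle Coeffs", 3, get_count("angle types"))
  dc <- section("Dihedral Coeffs", 5, get_count("dihedral types"))
  b <- section("Bonds", 4, nb)
  if (!is.null(b)) sysr$bonds <- data.frame(i = as.integer(b[, 3]),
                                            j = as.integer(b[, 4]),
                                            l0 = bc[b[, 2], 3], kl = bc[b[, 2], 2])
  g <- section("Angles", 5, na_)
  if (!is.null(g)) sysr$angles <- data.frame(i = as.integer(g[, 3]),
                                             j = as.integer(g[, 4]),
                                             k = as.integer(g[, 5]),
                                             theta0 = ac[g[, 2], 3],
                                             ktheta = ac[g[, 2], 2])
  d <- section("Dihedrals", 6, nd)
  if (!is.null(d)) sysr$dihedrals <- data.frame(i = as.integer(d[, 3]),
                                                j = as.integer(d[, 4]),
                                                k = as.integer(d[, 5]),
                                                l = as.integer(d[, 6]),
                                                V1 = dc[d[, 2], 2], V2 = dc[d[, 2], 3],
                                                V3 = dc[d[, 2], 4], V4 = dc[d[, 2], 5])
  sysr
}

#' Write an SDF grid as a Gaussian cube file
#'
#' @param x a `bilff_sdf`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_cube <- function(x, path) {
  bohr <- 0.529177210903 * 100           # pm per bohr
  nb <- length(x$axes)
  step <- (x$axes[2] - x$axes[1]) / bohr
  orig <- (x$axes[1] - (x$axes[2] - x$axes[1]) / 2) / bohr
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bilff spatial distribution function (density in nm^-3)", con)
  writeLines("molecule-fixed frame; one dummy atom at the origin", con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1, orig, orig, orig), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nb, step, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nb, 0, step, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nb, 0, 0, step), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1, 0, 0, 0, 0), con)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    v <- x$density[i, j, ]
    for (s in seq(1, nb, by = 6))
      writeLines(paste(sprintf("%13.5e", v[s:min(s + 5, nb)]), collapse = " "), con)
  }
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration couples a composition, force-field sources, the
#' staged protocol and analysis requests. Unspecified fields take the
#' protocol defaults (0.5 fs timestep, 800 pm LJ cutoff, 100 fs Nose-Hoover
#' and 2000 fs barostat couplings, stages at 500 K / target temperature).
#'
#' @param path YAML file path.
#' @return named list with all defaults resolved.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- list(
    composition = list(),
    box_edge = NULL,
    forcefield = list(extra = character()),
    seed = 1,
    temperature = 350,
    dt = 0.5,
    cutoff = 800,
    electrostatics = "dsf",
    thermostat = list(kind = "nosehoover", tau = 100),
    barostat = list(tau = 2000, pressure = 1.01325),
    stages = list(scramble = 2, npt = 5, damp = 1, production = 10),
    save_every = 50,
    output = "trajectory.xyz")
  cfg <- utils::modifyList(defaults, user)
  if (!length(cfg$composition)) stop("run config must give a composition")
  if (is.null(cfg$box_edge)) stop("run config must give box_edge (pm)")
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
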