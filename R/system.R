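# Flattened periodic systems: per-atom parameter arrays, bonded term lists,
# 1-2/1-3/1-4 exclusion map, constraints and virtual sites, ready for the
# compiled engine.

#' Build a flattened periodic system from a composition
#'
#' Resolves every molecule template against the force field, concatenates the
#' per-atom parameters, enumerates bonded terms and constructs the
#' intramolecular exclusion map (pairs at bond-graph distance 1, 2 and 3 get
#' the 1-2, 1-3 and 1-4 scaling factors of the force field's exclusion
#' policy; rigid-molecule constraints and virtual-site attachments count as
#' graph edges). Positions can be supplied or generated later with
#' [pack_system()].
#'
#' @param comp a [composition()].
#' @param ff a `bilff_forcefield` resolving every species in `comp`.
#' @param pos optional N x 3 matrix of positions in Angstrom.
#' @return `bilff_system` object.
#' @export
build_system <- function(comp, ff, pos = NULL) {
  atoms <- list(); bonds <- list(); angles <- list(); dihedrals <- list()
  special <- list(); constraints <- list(); vsites <- list()
  off <- 0L; mol <- 0L
  for (s in seq_along(comp$species)) {
    tpl <- comp$templates[[s]]
    terms <- enumerate_bonded_terms(tpl, ff)
    q_ok <- template_charge(tpl, ff)
    if (abs(q_ok - tpl$net_charge_target) > 1e-6)
      stop(sprintf("template %s: net charge %.6f != target %.3f",
                   tpl$species, q_ok, tpl$net_charge_target))
    ty <- do.call(rbind, lapply(tpl$atoms$type, function(t)
      lookup_type(ff, tpl$species, t)))
    sp <- .template_exclusions(tpl, ff$exclusion_policy)
    na <- nrow(tpl$atoms)
    for (c_ in seq_len(comp$counts[s])) {
      mol <- mol + 1L
      atoms[[length(atoms) + 1]] <- data.frame(
        species = tpl$species, label = tpl$atoms$label, type = ty$type,
        class = ty$class, element = ty$element, mass = ty$mass, q = ty$q,
        sigma = ty$sigma, epsilon = ty$epsilon, mol_id = mol,
        virtual = ty$element == "M", stringsAsFactors = FALSE)
      shift <- function(d, cols) { d[cols] <- d[cols] + off; d }
      if (nrow(terms$bonds)) bonds[[length(bonds) + 1]] <-
        shift(terms$bonds, c("i", "j"))
      if (nrow(terms$angles)) angles[[length(angles) + 1]] <-
        shift(terms$angles, c("i", "j", "k"))
      if (nrow(terms$dihedrals)) dihedrals[[length(dihedrals) + 1]] <-
        shift(terms$dihedrals, c("i", "j", "k", "l"))
      if (nrow(sp)) special[[length(special) + 1]] <- shift(sp, c("i", "j"))
      if (!is.null(tpl$constraints)) constraints[[length(constraints) + 1]] <-
        shift(tpl$constraints, c("i", "j"))
      if (!is.null(tpl$vsite)) vsites[[length(vsites) + 1]] <- data.frame(
        idx = tpl$vsite$idx + off, o = tpl$vsite$o + off,
        h1 = tpl$vsite$h1 + off, h2 = tpl$vsite$h2 + off,
        gamma = tpl$vsite$gamma)
      off <- off + na
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  sys <- structure(list(
    atoms = bind(atoms, data.frame()),
    pos = pos,
    box = comp$box_edge / 100,   # pm -> Angstrom
    bonds = bind(bonds, data.frame(i = integer(), j = integer(),
                                   l0 = numeric(), kl = numeric())),
    angles = bind(angles, data.frame(i = integer(), j = integer(), k = integer(),
                                     theta0 = numeric(), ktheta = numeric())),
    dihedrals = bind(dihedrals, data.frame(i = integer(), j = integer(),
                                           k = integer(), l = integer(),
                                           V1 = numeric(), V2 = numeric(),
                                           V3 = numeric(), V4 = numeric())),
    special = bind(special, data.frame(i = integer(), j = integer(), f = numeric())),
    constraints = bind(constraints, data.frame(i = integer(), j = integer(),
                                               d = numeric())),
    vsites = bind(vsites, data.frame(idx = integer(), o = integer(),
                                     h1 = integer(), h2 = integer(),
                                     gamma = numeric())),
    composition = comp
  ), class = "bilff_system")
  rownames(sys$atoms) <- NULL
  if (!is.null(pos)) stopifnot(nrow(pos) == nrow(sys$atoms), all(is.finite(pos)))
  sys
}

# pairs at graph distance 1..3 with their scaling factor (only f < 1 kept)
.template_exclusions <- function(tpl, policy) {
  n <- nrow(tpl$atoms)
  adj <- .adjacency(tpl)
  out <- list()
  for (i in seq_len(n)) {
    dist <- rep.int(NA_integer_, n); dist[i] <- 0L; queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= 3L) next
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    j <- which(dist >= 1L & dist <= 3L & seq_len(n) > i)
    if (length(j)) out[[length(out) + 1]] <-
      data.frame(i = i, j = j, f = policy[dist[j]])
  }
  sp <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), f = numeric())
  sp[sp$f < 1, , drop = FALSE]
}

#' @export
print.bilff_system <- function(x, ...) {
  cat(sprintf("bilff system: %d atoms (%d molecules), box %.2f A%s\n",
              nrow(x$atoms), max(x$atoms$mol_id, 0), x$box,
              if (is.null(x$pos)) " [no coordinates]" else ""))
  cat(sprintf("  %d bonds, %d angles, %d dihedrals, %d constraints, %d virtual sites\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$constraints), nrow(x$vsites)))
  invisible(x)
}

#' Select atom indices of a system
#'
#' @param sys a `bilff_system` (or the topology of a trajectory).
#' @param species,type,element,label optional filters; each may be a vector.
#' @param real_only drop virtual (massless) sites, default TRUE.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(sys, species = NULL, type = NULL, element = NULL,
                         label = NULL, real_only = TRUE) {
  a <- sys$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(species)) keep <- keep & a$species %in% species
  if (!is.null(type)) keep <- keep & a$type %in% type
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(label)) keep <- keep & a$label %in% label
  if (real_only) keep <- keep & !a$virtual
  which(keep)
}

#' Number of kinetic degrees of freedom
#'
#' 3 per real atom, minus one per holonomic constraint, minus 3 for the
#' removed centre-of-mass motion.
#' @param sys a `bilff_system`.
#' @export
degrees_of_freedom <- function(sys) {
  3L * sum(!sys$atoms$virtual) - nrow(sys$constraints) - 3L
}

# ---- template reference coordinates -----------------------------------------

# three hydrogens of a methyl group: carbon at cpos, attached along -axis
.methyl_h <- function(cpos, axis, lch = 1.09) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * axis) * axis; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(axis[2] * t1[3] - axis[3] * t1[2],
          axis[3] * t1[1] - axis[1] * t1[3],
          axis[1] * t1[2] - axis[2] * t1[1])
  # tetrahedral: 33.3 deg above the axis-normal plane
  sapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
    cpos + lch * (0.3338 * axis + 0.9426 * (cos(phi) * t1 + sin(phi) * t2))) |> t()
}

.ring_xy <- function(idx_order, radius) {
  n <- length(idx_order)
  th <- pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  out <- matrix(0, max(idx_order), 3)
  out[idx_order, 1] <- radius * cos(th)
  out[idx_order, 2] <- radius * sin(th)
  out
}

# rough (pre-minimization) Cartesian coordinates for each template
.template_coords <- function(species) {
  out_from_center <- function(pos, base_idx, d) {
    u <- pos[base_idx, ] / sqrt(sum(pos[base_idx, ]^2))
    pos[base_idx, ] + d * u
  }
  if (species == "EMTr" || species == "EMIm") {
    n <- if (species == "EMTr") 18 else 19
    pos <- matrix(0, n, 3)
    pos[1:5, ] <- .ring_xy(1:5, 1.18)[1:5, ]
    if (species == "EMTr") {
      h_on <- c(4, 5); h_idx <- c(6, 7)
      ce1 <- 8; he <- c(9, 10); ce2 <- 11; he2 <- 12:14; cm <- 15; hm <- 16:18
      n_eth <- 1; n_met <- 3
    } else {
      pos[6, ] <- out_from_center(pos, 2, 1.08)          # H on C2
      h_on <- c(4, 5); h_idx <- c(7, 8)
      ce1 <- 9; he <- c(10, 11); ce2 <- 12; he2 <- 13:15; cm <- 16; hm <- 17:19
      n_eth <- 1; n_met <- 3
    }
    for (k in seq_along(h_on)) pos[h_idx[k], ] <- out_from_center(pos, h_on[k], 1.09)
    pos[ce1, ] <- out_from_center(pos, n_eth, 1.47)
    u <- pos[ce1, ] / sqrt(sum(pos[ce1, ]^2))
    pos[he[1], ] <- pos[ce1, ] + 1.09 * c(-u[2], u[1], 0) * 0.45 + c(0, 0, 0.98)
    pos[he[2], ] <- pos[ce1, ] + 1.09 * c(u[2], -u[1], 0) * 0.45 + c(0, 0, -0.98)
    pos[ce2, ] <- pos[ce1, ] + 1.53 * c(u[1] * 0.5, u[2] * 0.5, 0.866)
    pos[he2, ] <- .methyl_h(pos[ce2, ], pos[ce2, ] - pos[ce1, ])
    pos[cm, ] <- out_from_center(pos, n_met, 1.47)
    pos[hm, ] <- .methyl_h(pos[cm, ], pos[cm, ] / sqrt(sum(pos[cm, ]^2)))
    return(pos)
  }
  if (species == "OBz") {
    pos <- matrix(0, 14, 3)
    ring <- .ring_xy(c(4, 5, 7, 9, 8, 6), 1.387)
    pos[c(4, 5, 6, 7, 8, 9), ] <- ring[c(4, 5, 6, 7, 8, 9), ]
    pos[1, ] <- out_from_center(pos, 4, 1.504)                # CO
    u <- pos[1, ] / sqrt(sum(pos[1, ]^2))
    t <- c(-u[2], u[1], 0)
    pos[2, ] <- pos[1, ] + 1.282 * (cos(63 * pi / 180) * u + sin(63 * pi / 180) * t)
    pos[3, ] <- pos[1, ] + 1.282 * (cos(63 * pi / 180) * u - sin(63 * pi / 180) * t)
    for (k in 1:5) pos[c(10, 11, 12, 13, 14)[k], ] <-
      out_from_center(pos, c(5, 6, 7, 8, 9)[k], 1.088)
    return(pos)
  }
  if (species == "OAc") {
    pos <- matrix(0, 7, 3)
    pos[1, ] <- c(0, 0.76, 0)                                  # CO
    pos[4, ] <- c(0, -0.76, 0)                                 # CH3 C
    u <- c(0, 1, 0); t <- c(1, 0, 0)
    pos[2, ] <- pos[1, ] + 1.282 * (cos(63 * pi / 180) * u + sin(63 * pi / 180) * t)
    pos[3, ] <- pos[1, ] + 1.282 * (cos(63 * pi / 180) * u - sin(63 * pi / 180) * t)
    pos[5:7, ] <- .methyl_h(pos[4, ], pos[4, ] - pos[1, ])
    return(pos)
  }
  if (species == "TIP4PEW") {
    ang <- 104.52 * pi / 180; doh <- 0.9572
    return(rbind(c(0, 0, 0),
                 c(doh * sin(ang / 2), doh * cos(ang / 2), 0),
                 c(-doh * sin(ang / 2), doh * cos(ang / 2), 0),
                 c(0, 0.125, 0)))
  }
  stop("no reference coordinates for species ", species)
}

# relaxed single-molecule coordinates (vacuum minimization), cached per call
.relaxed_coords <- function(species, ff) {
  pos <- .template_coords(species)
  if (species == "TIP4PEW") return(pos)
  comp1 <- composition(box_edge = 1e4)   # 100 A box, effectively vacuum
  comp1$species <- species; comp1$counts <- 1L
  comp1$templates <- list(build_molecule(species))
  sys1 <- build_system(comp1, ff, pos = pos)
  minimize_system(sys1, ff, steps = 400, max_disp = 0.05)$pos
}

#' Pack molecules into the simulation box
#'
#' Seeded, deterministic box construction without external tools. Molecules
#' are relaxed in vacuum, then placed with random orientations either on a
#' jittered lattice (`method = "lattice"`, robust at liquid densities; any
#' residual contacts are removed by the capped-displacement minimizer) or by
#' random insertion with overlap rejection (`method = "random"`, minimum
#' intermolecular distance `min_dist`).
#'
#' @param sys a `bilff_system` without coordinates.
#' @param ff the force field (used for the vacuum relaxation and contact
#'   minimization).
#' @param seed integer seed; identical seeds give identical packings.
#' @param method `"lattice"` or `"random"`.
#' @param min_dist minimum interatomic distance for random insertion, Angstrom.
#' @param tries insertion attempts per molecule for `method = "random"`.
#' @param relax_steps capped-displacement minimization steps after placement.
#' @return the system with `pos` set.
#' @export
pack_system <- function(sys, ff, seed = 1, method = c("lattice", "random"),
                        min_dist = 2.0, tries = 2000, relax_steps = 200) {
  method <- match.arg(method)
  set.seed(seed)
  L <- sys$box
  a <- sys$atoms
  mols <- split(seq_len(nrow(a)), a$mol_id)
  coords_cache <- list()
  get_coords <- function(sp) {
    if (is.null(coords_cache[[sp]]))
      coords_cache[[sp]] <<- .relaxed_coords(sp, ff)
    coords_cache[[sp]]
  }
  pos <- matrix(NA_real_, nrow(a), 3)
  nmol <- length(mols)
  if (method == "lattice") {
    side <- ceiling(nmol^(1 / 3))
    cells <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                   z = seq_len(side))) - 0.5
    cells <- cells * (L / side)
    cells <- cells[sample(nrow(cells), nmol), , drop = FALSE]
    for (m in seq_len(nmol)) {
      idx <- mols[[m]]
      xyz <- get_coords(a$species[idx[1]])
      xyz <- .center_mol(xyz)
      xyz <- xyz %*% .random_rotation()
      jit <- runif(3, -0.15, 0.15) * (L / side)
      pos[idx, ] <- sweep(xyz, 2, cells[m, ] + jit, `+`)
    }
  } else {
    placed <- 0
    for (m in seq_len(nmol)) {
      idx <- mols[[m]]
      xyz <- .center_mol(get_coords(a$species[idx[1]]))
      ok <- FALSE
      for (t_ in seq_len(tries)) {
        cand <- sweep(xyz %*% .random_rotation(), 2, runif(3, 0, L), `+`)
        if (placed == 0 ||
            .min_dist_pbc(cand, pos[seq_len(placed), , drop = FALSE], L) >= min_dist) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("random insertion failed for molecule ", m,
                    " after ", tries, " tries; lower the density or use lattice packing")
      pos[idx, ] <- cand
      placed <- placed + length(idx)
    }
  }
  sys$pos <- pos
  if (relax_steps > 0)
    sys <- minimize_system(sys, ff, steps = relax_steps, max_disp = 0.1)
  sys
}

.center_mol <- function(xyz) sweep(xyz, 2, colMeans(xyz))

.random_rotation <- function() {
  # uniform rotation from a random unit quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.min_dist_pbc <- function(xa, xb, L) {
  mind <- Inf
  for (r in seq_len(nrow(xa))) {
    d <- sweep(xb, 2, xa[r, ])
    d <- d - L * round(d / L)
    mind <- min(mind, sqrt(min(rowSums(d^2))))
  }
  mind
}

#' Maxwell-Boltzmann initial velocities
#'
#' Seeded Gaussian velocities at the target temperature with centre-of-mass
#' motion removed and kinetic energy rescaled to the exact target.
#'
#' @param sys a `bilff_system`.
#' @param temperature target temperature, K.
#' @param seed integer seed.
#' @return N x 3 velocity matrix in Angstrom per 100 fs (internal units);
#'   virtual sites get zero velocity.
#' @export
init_velocities <- function(sys, temperature, seed = 1) {
  set.seed(seed)
  n <- nrow(sys$atoms)
  m <- sys$atoms$mass
  real <- !sys$atoms$virtual
  v <- matrix(0, n, 3)
  kB <- bilff_constants$kB
  v[real, ] <- rnorm(3 * sum(real)) * sqrt(kB * temperature / m[real])
  # remove COM drift
  p <- colSums(v[real, , drop = FALSE] * m[real])
  v[real, ] <- sweep(v[real, , drop = FALSE], 2, p / sum(m[real]))
  ke <- 0.5 * sum(m[real] * rowSums(v[real, , drop = FALSE]^2))
  nf <- degrees_of_freedom(sys)
  target <- 0.5 * nf * kB * temperature
  if (ke > 0) v[real, ] <- v[real, , drop = FALSE] * sqrt(target / ke)
  v
}

#' Construct a bare system from raw per-atom data
#'
#' Low-level constructor for toy and fixture systems (LJ fluids, point
#' charges, test crystals) that are not built from molecule templates.
#'
#' @param pos N x 3 position matrix, Angstrom.
#' @param box cubic box edge in Angstrom; `0` for an isolated (non-periodic)
#'   system.
#' @param q,sigma,epsilon,mass per-atom vectors (recycled); defaults are
#'   neutral, LJ-less unit-mass particles.
#' @param mol_id integer molecule ids (default: each atom its own molecule).
#' @param bonds,angles,dihedrals,special,constraints,vsites optional data
#'   frames in the same layout as produced by [build_system()].
#' @return `bilff_system` object.
#' @export
raw_system <- function(pos, box, q = 0, sigma = 1, epsilon = 0, mass = 1,
                       mol_id = NULL, bonds = NULL, angles = NULL,
                       dihedrals = NULL, special = NULL, constraints = NULL,
                       vsites = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.null(mol_id)) mol_id <- seq_len(n)
  atoms <- data.frame(
    species = rep("X", n), label = sprintf("X%d", seq_len(n)),
    type = rep("X", n), class = rep("X", n),
    element = rep("X", n), mass = rep_len(mass, n), q = rep_len(q, n),
    sigma = rep_len(sigma, n), epsilon = rep_len(epsilon, n),
    mol_id = mol_id, virtual = rep(FALSE, n), stringsAsFactors = FALSE)
  proto <- list(
    bonds = data.frame(i = integer(), j = integer(), l0 = numeric(), kl = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), ktheta = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), V1 = numeric(), V2 = numeric(),
                           V3 = numeric(), V4 = numeric()),
    special = data.frame(i = integer(), j = integer(), f = numeric()),
    constraints = data.frame(i = integer(), j = integer(), d = numeric()),
    vsites = data.frame(idx = integer(), o = integer(), h1 = integer(),
                        h2 = integer(), gamma = numeric()))
  structure(list(
    atoms = atoms, pos = pos, box = box,
    bonds = if (is.null(bonds)) proto$bonds else bonds,
    angles = if (is.null(angles)) proto$angles else angles,
    dihedrals = if (is.null(dihedrals)) proto$dihedrals else dihedrals,
    special = if (is.null(special)) proto$special else special,
    constraints = if (is.null(constraints)) proto$constraints else constraints,
    vsites = if (is.null(vsites)) proto$vsites else vsites,
    composition = NULL
  ), class = "bilff_system")
}
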