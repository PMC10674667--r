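# Shared helpers: independent oracles and toy-system builders.

# force field with every bundled auxiliary parameter file merged
ff_full <- function() {
  load_bilff(extra = vapply(c("oac_synthetic.prm", "emim_synthetic.prm",
                              "tip4pew.prm"), bilff_extdata, character(1)))
}

# central-difference gradient of the total energy
num_grad <- function(sys, opts, h = 1e-5) {
  g <- matrix(0, nrow(sys$pos), 3)
  for (i in seq_len(nrow(sys$pos))) {
    for (c in 1:3) {
      sp <- sys; sp$pos[i, c] <- sp$pos[i, c] + h
      sm <- sys; sm$pos[i, c] <- sm$pos[i, c] - h
      g[i, c] <- (total_energy_forces(sp, opts)$total -
                  total_energy_forces(sm, opts)$total) / (2 * h)
    }
  }
  g
}

# independent brute-force enumeration of angles/dihedrals from a bond list
brute_terms <- function(bonds, n) {
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(bonds))) {
    adj[bonds[r, 1], bonds[r, 2]] <- TRUE
    adj[bonds[r, 2], bonds[r, 1]] <- TRUE
  }
  angles <- list()
  for (j in seq_len(n)) for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i < k && i != j && k != j && adj[i, j] && adj[j, k])
      angles[[length(angles) + 1]] <- c(i, j, k)
  }
  dihedrals <- list()
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j != k && adj[j, k]) for (i in seq_len(n)) for (l in seq_len(n)) {
      if (i != j && i != k && l != j && l != k && i != l &&
          adj[i, j] && adj[k, l] && j < k)
        dihedrals[[length(dihedrals) + 1]] <- c(i, j, k, l)
    }
  }
  list(angles = angles, dihedrals = dihedrals)
}

# canonical form of a term index tuple (reversal-invariant)
canon <- function(x) {
  r <- rev(x)
  if (paste(x, collapse = "-") <= paste(r, collapse = "-")) x else r
}
canon_set <- function(rows) sort(vapply(rows, function(x)
  paste(canon(x), collapse = "-"), character(1)))

# rock-salt toy crystal (8 atoms, unit charges)
nacl_crystal <- function(a = 5.64) {
  fr <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
              c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
  raw_system(fr * a, box = a, q = c(1, 1, 1, 1, -1, -1, -1, -1),
             epsilon = 0, mass = 1)
}

# cubic-lattice LJ fluid (argon-like)
lj_fluid <- function(n = 100, spacing = 6, box = 30) {
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * spacing + 1
  raw_system(g[seq_len(n), ], box = box, sigma = 3.4, epsilon = 0.996,
             mass = 39.95)
}

# single-molecule system in a large box
vacuum_molecule <- function(species, ff, jitter = 0, seed = 1) {
  comp <- composition(box_edge = 1e4)
  comp$species <- species
  comp$counts <- 1L
  comp$templates <- list(build_molecule(species))
  pos <- bilff:::.template_coords(species)
  if (jitter > 0) {
    set.seed(seed)
    pos <- pos + matrix(rnorm(length(pos), 0, jitter), nrow(pos), 3)
  }
  build_system(comp, ff, pos = pos)
}
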