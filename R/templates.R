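# Hand-curated molecule templates. Atom typing for arbitrary molecules is
# deliberately out of scope; the five species below are the supported set.

.template_atoms <- function(species, type, label = type) {
  data.frame(label = label, type = type, stringsAsFactors = FALSE)
}

#' Build a molecule template
#'
#' Returns the molecular graph (ordered atoms with type assignment, bond
#' list, rigid-body constraints for water) for one of the supported species:
#' \describe{
#'   \item{EMTr}{1-ethyl-3-methyl-1,2,3-triazolium cation, net +0.82 e.}
#'   \item{OBz}{benzoate anion, net -0.82 e.}
#'   \item{OAc}{acetate anion, net -0.82 e (needs merged parameters, see
#'     `bilff_extdata("oac_synthetic.prm")`).}
#'   \item{EMIm}{1-ethyl-3-methylimidazolium cation, net +0.82 e (needs
#'     merged parameters, see `bilff_extdata("emim_synthetic.prm")`).}
#'   \item{TIP4PEW}{rigid four-site water (massless M charge site on the
#'     bisector; O-H 0.9572 A, H-O-H 104.52 deg held by SHAKE), net 0.}
#' }
#'
#' @param species one of `"EMTr"`, `"OBz"`, `"OAc"`, `"EMIm"`, `"TIP4PEW"`.
#' @return `bilff_template`: list with `species`, `atoms` (data frame of
#'   label/type), `bonds` (2-column index matrix), `constraints` (data frame
#'   i/j/d or NULL), `vsite` (list idx/o/h1/h2/gamma or NULL),
#'   `net_charge_target` (e).
#' @export
build_molecule <- function(species) {
  b <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  tpl <- switch(species,
    EMTr = list(
      atoms = .template_atoms("EMTr",
        c("NA", "NR", "NA", "CW", "CW", "HCW", "HCW",
          "C1", "H1", "H1", "CE", "HC", "HC", "HC",
          "C1", "H1", "H1", "H1"),
        c("N1", "N2", "N3", "C4", "C5", "H4", "H5",
          "CE1", "HE11", "HE12", "CE2", "HE21", "HE22", "HE23",
          "CM", "HM1", "HM2", "HM3")),
      bonds = b(1,2, 2,3, 3,4, 4,5, 5,1, 4,6, 5,7,
                1,8, 8,9, 8,10, 8,11, 11,12, 11,13, 11,14,
                3,15, 15,16, 15,17, 15,18),
      net = 0.82),
    OBz = list(
      atoms = .template_atoms("OBz",
        c("CO", "O2", "O2", "C1", "C2", "C2", "C3", "C3", "C4",
          "H2", "H2", "H3", "H3", "H4"),
        c("C7", "O1", "O2", "C1", "C2a", "C2b", "C3a", "C3b", "C4",
          "H2a", "H2b", "H3a", "H3b", "H4")),
      bonds = b(1,2, 1,3, 1,4, 4,5, 4,6, 5,7, 6,8, 7,9, 8,9,
                5,10, 6,11, 7,12, 8,13, 9,14),
      net = -0.82),
    OAc = list(
      atoms = .template_atoms("OAc",
        c("CO", "O2", "O2", "CT", "HC", "HC", "HC"),
        c("C1", "O1", "O2", "C2", "H1", "H2", "H3")),
      bonds = b(1,2, 1,3, 1,4, 4,5, 4,6, 4,7),
      net = -0.82),
    EMIm = list(
      atoms = .template_atoms("EMIm",
        c("NA", "CR", "NA", "CW", "CW", "HCR", "HCW", "HCW",
          "C1", "H1", "H1", "CE", "HC", "HC", "HC",
          "C1", "H1", "H1", "H1"),
        c("N1", "C2", "N3", "C4", "C5", "H2", "H4", "H5",
          "CE1", "HE11", "HE12", "CE2", "HE21", "HE22", "HE23",
          "CM", "HM1", "HM2", "HM3")),
      bonds = b(1,2, 2,3, 3,4, 4,5, 5,1, 2,6, 4,7, 5,8,
                1,9, 9,10, 9,11, 9,12, 12,13, 12,14, 12,15,
                3,16, 16,17, 16,18, 16,19),
      net = 0.82),
    TIP4PEW = {
      doh <- 0.9572; ang <- 104.52 * pi / 180
      list(
        atoms = .template_atoms("TIP4PEW", c("OW", "HW", "HW", "MW"),
                                c("O", "H1", "H2", "M")),
        bonds = matrix(numeric(0), ncol = 2),
        constraints = data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                 d = c(doh, doh, 2 * doh * sin(ang / 2))),
        vsite = list(idx = 4, o = 1, h1 = 2, h2 = 3,
                     gamma = 0.1250 / (2 * doh * cos(ang / 2))),
        net = 0)
    },
    stop("unknown species '", species, "'")
  )
  structure(list(
    species = species,
    atoms = tpl$atoms,
    bonds = tpl$bonds,
    constraints = if (!is.null(tpl$constraints)) tpl$constraints,
    vsite = if (!is.null(tpl$vsite)) tpl$vsite,
    net_charge_target = tpl$net
  ), class = "bilff_template")
}

#' @export
print.bilff_template <- function(x, ...) {
  cat(sprintf("bilff template %s: %d atoms, %d bonds, target net charge %+.2f e\n",
              x$species, nrow(x$atoms), nrow(x$bonds), x$net_charge_target))
  invisible(x)
}

# adjacency list from a bond matrix (bonds + constraints define connectivity)
.adjacency <- function(template) {
  n <- nrow(template$atoms)
  edges <- template$bonds
  if (!is.null(template$constraints))
    edges <- rbind(edges, as.matrix(template$constraints[, c("i", "j")]))
  if (!is.null(template$vsite))
    edges <- rbind(edges, c(template$vsite$idx, template$vsite$o))
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, unique)
}

.check_connected <- function(template) {
  n <- nrow(template$atoms)
  if (n == 1) return(invisible(TRUE))
  adj <- .adjacency(template)
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) stop("molecular graph of ", template$species, " is not connected")
  invisible(TRUE)
}

#' Enumerate bonded interaction terms of a template
#'
#' Angles are all connected triples and proper dihedrals all connected
#' quadruples of the covalent graph (constraints of rigid molecules do not
#' generate angle/torsion terms). Each term is mapped to its parameter row by
#' atom class; a term with no parameter row is an error listing the class
#' tuple.
#'
#' @param template a `bilff_template`.
#' @param ff a `bilff_forcefield` used for class assignment and parameter
#'   lookup.
#' @return list with data frames `bonds` (i, j, l0, kl), `angles`
#'   (i, j, k, theta0, ktheta), `dihedrals` (i, j, k, l, V1..V4).
#' @export
enumerate_bonded_terms <- function(template, ff) {
  .check_connected(template)
  cls <- vapply(template$atoms$type, function(t)
    lookup_type(ff, template$species, t)$class, character(1))
  nb <- nrow(template$bonds)
  adj <- vector("list", nrow(template$atoms))
  if (nb > 0) {
    for (r in seq_len(nb)) {
      i <- template$bonds[r, 1]; j <- template$bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  bonds <- if (nb > 0) {
    p <- lapply(seq_len(nb), function(r) {
      i <- template$bonds[r, 1]; j <- template$bonds[r, 2]
      cbind(i = i, j = j, lookup_bond(ff, cls[i], cls[j])[, c("l0", "kl")])
    })
    do.call(rbind, p)
  } else data.frame(i = integer(), j = integer(), l0 = numeric(), kl = numeric())

  angles <- list()
  for (j in seq_along(adj)) {
    nbs <- adj[[j]]
    if (length(nbs) >= 2) {
      cmb <- utils::combn(sort(nbs), 2)
      for (c_ in seq_len(ncol(cmb))) {
        i <- cmb[1, c_]; k <- cmb[2, c_]
        angles[[length(angles) + 1]] <-
          cbind(i = i, j = j, k = k,
                lookup_angle(ff, cls[i], cls[j], cls[k])[, c("theta0", "ktheta")])
      }
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), ktheta = numeric())

  dihedrals <- list()
  if (nb > 0) {
    for (r in seq_len(nb)) {
      j <- template$bonds[r, 1]; k <- template$bonds[r, 2]
      for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
        if (i == l) next   # three-membered ring guard
        dihedrals[[length(dihedrals) + 1]] <-
          cbind(i = i, j = j, k = k, l = l,
                lookup_torsion(ff, cls[i], cls[j], cls[k], cls[l])[,
                  c("V1", "V2", "V3", "V4")])
      }
    }
  }
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               V1 = numeric(), V2 = numeric(), V3 = numeric(), V4 = numeric())
  rownames(bonds) <- rownames(angles) <- rownames(dihedrals) <- NULL
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

#' Net partial charge of a template under a force field
#'
#' @param template a `bilff_template`.
#' @param ff a `bilff_forcefield`.
#' @return net charge in e.
#' @export
template_charge <- function(template, ff) {
  sum(vapply(template$atoms$type, function(t)
    lookup_type(ff, template$species, t)$q, numeric(1)))
}

#' Molar mass of a template
#'
#' @param template a `bilff_template`.
#' @param ff optional force field (used for element assignment; defaults to
#'   [load_bilff()] with all bundled auxiliary files).
#' @return molar mass in g/mol.
#' @export
molar_mass <- function(template, ff = NULL) {
  if (is.null(ff)) ff <- .ff_full()
  sum(vapply(template$atoms$type, function(t)
    lookup_type(ff, template$species, t)$mass, numeric(1)))
}

# embedded set + every bundled auxiliary parameter file
.ff_full <- function() {
  load_bilff(extra = vapply(c("oac_synthetic.prm", "emim_synthetic.prm",
                              "tip4pew.prm"), bilff_extdata, character(1)))
}

#' System composition
#'
#' A composition is a list of (template, count) pairs plus a cubic box edge,
#' mirroring how simulated systems are specified (e.g. 36 ion pairs in a
#' 2121 pm box).
#'
#' @param ... named integer counts, names being species (e.g.
#'   `EMTr = 36, OAc = 36`).
#' @param box_edge cubic box edge in pm.
#' @return `bilff_composition` object.
#' @examples
#' comp <- composition(EMTr = 36, OAc = 36, box_edge = 2121)
#' system_density(comp)   # ~1.072 g/cm^3
#' @export
composition <- function(..., box_edge) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)   # an empty box is permitted
  stopifnot(all(counts > 0), box_edge > 0)
  structure(list(
    species = names(counts),
    counts = as.integer(counts),
    templates = lapply(names(counts), build_molecule),
    box_edge = box_edge
  ), class = "bilff_composition")
}

#' @export
print.bilff_composition <- function(x, ...) {
  cat("bilff composition:",
      paste(sprintf("%d %s", x$counts, x$species), collapse = " + "),
      sprintf("in a %.0f pm box\n", x$box_edge))
  invisible(x)
}

#' Mass density of a composition
#'
#' rho = sum(count * molar mass) / (N_A * box volume).
#'
#' @param comp a `bilff_composition`.
#' @param ff optional force field for element assignment.
#' @return density in g/cm^3.
#' @export
system_density <- function(comp, ff = NULL) {
  if (is.null(ff)) ff <- .ff_full()
  m <- sum(comp$counts * vapply(comp$templates, molar_mass, numeric(1), ff = ff))
  v_cm3 <- (comp$box_edge * 1e-10)^3   # pm -> cm
  (m / bilff_constants$avogadro) / v_cm3
}
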