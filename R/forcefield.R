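# Force-field container and parameter-file handling.

.norm_pair <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}
.norm_triple <- function(a, b, c) {
  ifelse(a <= c, paste(a, b, c, sep = "-"), paste(c, b, a, sep = "-"))
}
.norm_quad <- function(a, b, c, d) {
  fwd <- paste(a, b, c, d, sep = "-")
  rev <- paste(d, c, b, a, sep = "-")
  ifelse(fwd <= rev, fwd, rev)
}

#' Load the BILFF force field
#'
#' Returns the embedded parameter set for \[EMTr\]+ and \[OBz\]- (atom types
#' with partial charges and Lennard-Jones parameters; bond, angle and torsion
#' parameters keyed by atom class). Additional parameter files, e.g. for
#' \[OAc\]-, \[EMIm\]+ or TIP4P-EW water, can be merged in; a merge that
#' redefines an existing key with a different value is an error.
#'
#' @param extra character vector of parameter-file paths to merge (see
#'   [read_forcefield()] for the format). The files shipped under
#'   `system.file("extdata", package = "bilff")` cover TIP4P-EW water and
#'   synthetic stand-in sets for \[OAc\]- and \[EMIm\]+.
#' @param exclusion_policy numeric length-3 vector of (1-2, 1-3, 1-4) scaling
#'   factors applied to both Lennard-Jones and Coulomb intramolecular
#'   interactions. Default is the OPLS-AA convention `c(0, 0, 0.5)`.
#' @return An object of class `bilff_forcefield`: a list with data frames
#'   `types`, `bonds`, `angles`, `torsions`, plus `exclusion_policy` and
#'   `combining_rule` (`"geometric"`).
#' @examples
#' ff <- load_bilff()
#' lookup_type(ff, "OBz", "O2")$q      # -0.550
#' lookup_bond(ff, "NA", "NR")$l0      # 1.344
#' @export
load_bilff <- function(extra = character(), exclusion_policy = c(0, 0, 0.5)) {
  stopifnot(length(exclusion_policy) == 3,
            all(exclusion_policy >= 0 & exclusion_policy <= 1))
  ff <- structure(list(
    types = .bilff_types(),
    bonds = .bilff_bonds(),
    angles = .bilff_angles(),
    torsions = .bilff_torsions(),
    exclusion_policy = as.numeric(exclusion_policy),
    combining_rule = "geometric"
  ), class = "bilff_forcefield")
  for (f in extra) ff <- merge_forcefield(ff, read_forcefield(f))
  validate_forcefield(ff)
  ff
}

validate_forcefield <- function(ff) {
  t <- ff$types
  if (any(t$sigma <= 0)) stop("sigma must be > 0")
  if (any(t$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(abs(t$q) >= 2)) stop("|q| must be < 2 e")
  if (anyDuplicated(paste(t$species, t$type))) stop("duplicate atom type")
  if (any(ff$bonds$l0 <= 0) || any(ff$bonds$kl <= 0)) stop("invalid bond parameters")
  if (any(ff$angles$theta0 <= 0) || any(ff$angles$theta0 >= 180) ||
      any(ff$angles$ktheta <= 0)) stop("invalid angle parameters")
  invisible(ff)
}

#' @export
print.bilff_forcefield <- function(x, ...) {
  cat("BILFF force field (OPLS-AA form, geometric combining rules)\n")
  cat(sprintf("  %d atom types over species: %s\n", nrow(x$types),
              paste(unique(x$types$species), collapse = ", ")))
  cat(sprintf("  %d bond, %d angle, %d torsion parameter rows\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  cat(sprintf("  1-2/1-3/1-4 scaling: %s\n",
              paste(format(x$exclusion_policy), collapse = " / ")))
  invisible(x)
}

#' Look up an atom type
#'
#' @param ff a `bilff_forcefield`.
#' @param species species name (e.g. `"EMTr"`). Alias types CM/HM/HE of the
#'   cation resolve to C1/H1/HC.
#' @param type atom type name (e.g. `"HCW"`).
#' @return one-row data frame with `q`, `sigma`, `epsilon`, `mass`, `class`,
#'   `element`.
#' @export
lookup_type <- function(ff, species, type) {
  if (species == "EMTr") {
    aliases <- c(CM = "C1", HM = "H1", HE = "HC")
    if (type %in% names(aliases)) type <- unname(aliases[[type]])
  }
  i <- which(ff$types$species == species & ff$types$type == type)
  if (length(i) != 1) stop("unknown atom type ", species, ".", type)
  ff$types[i, , drop = FALSE]
}

#' Look up bonded parameters (symmetric under tuple reversal)
#'
#' @param ff a `bilff_forcefield`.
#' @param c1,c2,c3,c4 atom class labels.
#' @return one-row data frame of parameters, or an error if the tuple has no
#'   parameter row.
#' @export
lookup_bond <- function(ff, c1, c2) {
  key <- .norm_pair(c1, c2)
  i <- which(.norm_pair(ff$bonds$class1, ff$bonds$class2) == key)
  if (length(i) != 1) stop("no bond parameters for class pair ", c1, "-", c2)
  ff$bonds[i, , drop = FALSE]
}

#' @rdname lookup_bond
#' @export
lookup_angle <- function(ff, c1, c2, c3) {
  key <- .norm_triple(c1, c2, c3)
  i <- which(.norm_triple(ff$angles$class1, ff$angles$class2, ff$angles$class3) == key)
  if (length(i) != 1) stop("no angle parameters for class triple ",
                           paste(c1, c2, c3, collapse = "-"))
  ff$angles[i, , drop = FALSE]
}

#' @rdname lookup_bond
#' @export
lookup_torsion <- function(ff, c1, c2, c3, c4) {
  key <- .norm_quad(c1, c2, c3, c4)
  i <- which(.norm_quad(ff$torsions$class1, ff$torsions$class2,
                        ff$torsions$class3, ff$torsions$class4) == key)
  if (length(i) != 1) stop("no torsion parameters for class quad ",
                           paste(c1, c2, c3, c4, sep = "-"))
  ff$torsions[i, , drop = FALSE]
}

#' Geometric-mean Lennard-Jones combining rule
#'
#' Cross parameters are the geometric means `sigma_ij = sqrt(sigma_i sigma_j)`
#' and `epsilon_ij = sqrt(epsilon_i epsilon_j)`.
#'
#' @param type_a,type_b one-row atom-type data frames as returned by
#'   [lookup_type()] (any list with `sigma` and `epsilon` works).
#' @return named numeric vector `c(sigma, epsilon)` in Angstrom / kJ/mol.
#' @examples
#' ff <- load_bilff()
#' combine_lj(lookup_type(ff, "EMTr", "HCW"), lookup_type(ff, "OBz", "O2"))
#' @export
combine_lj <- function(type_a, type_b) {
  for (t in list(type_a, type_b)) {
    if (is.null(t$sigma) || is.null(t$epsilon) || is.na(t$sigma) || is.na(t$epsilon))
      stop("missing Lennard-Jones parameters for type ",
           if (!is.null(t$type)) t$type else "<unnamed>")
  }
  c(sigma = sqrt(type_a$sigma * type_b$sigma),
    epsilon = sqrt(type_a$epsilon * type_b$epsilon))
}

#' Merge two force fields
#'
#' Rows with new keys are appended. A key present in both with identical
#' values is kept once; a key present in both with different values is a
#' merge-conflict error.
#'
#' @param ff,extra `bilff_forcefield` objects (or the bare list structure for
#'   `extra`, as produced by [read_forcefield()]).
#' @return merged `bilff_forcefield`.
#' @export
merge_forcefield <- function(ff, extra) {
  merge_tab <- function(a, b, keycols, what) {
    if (is.null(b) || nrow(b) == 0) return(a)
    keyfun <- switch(what,
      types = function(d) paste(d$species, d$type),
      bonds = function(d) .norm_pair(d$class1, d$class2),
      angles = function(d) .norm_triple(d$class1, d$class2, d$class3),
      torsions = function(d) .norm_quad(d$class1, d$class2, d$class3, d$class4))
    ka <- keyfun(a); kb <- keyfun(b)
    for (k in intersect(ka, kb)) {
      ra <- a[ka == k, setdiff(names(a), keycols), drop = FALSE]
      rb <- b[kb == k, setdiff(names(b), keycols), drop = FALSE]
      num <- intersect(names(ra)[vapply(ra, is.numeric, TRUE)], names(rb))
      if (any(abs(unlist(ra[num]) - unlist(rb[num])) > 1e-9))
        stop("merge conflict for ", what, " key '", k, "'")
    }
    rbind(a, b[!(kb %in% ka), names(a), drop = FALSE])
  }
  ff$types <- merge_tab(ff$types, extra$types, c("species", "type"), "types")
  ff$bonds <- merge_tab(ff$bonds, extra$bonds, c("class1", "class2"), "bonds")
  ff$angles <- merge_tab(ff$angles, extra$angles,
                         c("class1", "class2", "class3"), "angles")
  ff$torsions <- merge_tab(ff$torsions, extra$torsions,
                           c("class1", "class2", "class3", "class4"), "torsions")
  validate_forcefield(ff)
  ff
}

#' Read / write a plain-text parameter file
#'
#' The format mirrors the published table structure: whitespace-separated
#' tables under the section headers `[types]`, `[bonds]`, `[angles]`,
#' `[torsions]`, with `#` comments. Columns:
#' \itemize{
#'   \item types: species type class element q sigma epsilon
#'   \item bonds: class1 class2 l0 kl  (Angstrom, kJ mol-1 A-2)
#'   \item angles: class1 class2 class3 theta0 ktheta  (deg, kJ mol-1 rad-2)
#'   \item torsions: class1..class4 V1 V2 V3 V4  (kJ/mol)
#' }
#'
#' @param path file path.
#' @return `read_forcefield`: a `bilff_forcefield`-shaped list (no exclusion
#'   policy; intended for merging).
#' @export
read_forcefield <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- cumsum(grepl("^\\[", lines))
  out <- list(types = NULL, bonds = NULL, angles = NULL, torsions = NULL)
  headers <- list(
    types = c("species", "type", "class", "element", "q", "sigma", "epsilon"),
    bonds = c("class1", "class2", "l0", "kl"),
    angles = c("class1", "class2", "class3", "theta0", "ktheta"),
    torsions = c("class1", "class2", "class3", "class4", "V1", "V2", "V3", "V4"))
  for (s in unique(sec[sec > 0])) {
    block <- lines[sec == s]
    name <- gsub("\\[|\\]", "", block[1])
    if (!name %in% names(headers))
      stop("unknown section [", name, "] in ", path)
    if (length(block) == 1) next
    tab <- read.table(text = paste(block[-1], collapse = "\n"),
                      stringsAsFactors = FALSE, na.strings = character(0))
    if (ncol(tab) != length(headers[[name]]))
      stop("section [", name, "] in ", path, ": expected ",
           length(headers[[name]]), " columns, got ", ncol(tab))
    names(tab) <- headers[[name]]
    out[[name]] <- tab
  }
  if (!is.null(out$types)) out$types$mass <- atomic_weight(out$types$element)
  structure(out, class = "bilff_forcefield")
}

#' @rdname read_forcefield
#' @param ff force field to serialize.
#' @export
write_forcefield <- function(ff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bilff parameter file", con)
  wr <- function(name, tab, cols) {
    writeLines(paste0("[", name, "]"), con)
    fmt <- tab[, cols, drop = FALSE]
    write.table(format(fmt, digits = 12, trim = TRUE, scientific = FALSE),
                con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  wr("types", ff$types, c("species", "type", "class", "element", "q", "sigma", "epsilon"))
  wr("bonds", ff$bonds, c("class1", "class2", "l0", "kl"))
  wr("angles", ff$angles, c("class1", "class2", "class3", "theta0", "ktheta"))
  wr("torsions", ff$torsions,
     c("class1", "class2", "class3", "class4", "V1", "V2", "V3", "V4"))
  invisible(path)
}

#' Path to a bundled parameter or example file
#'
#' @param file file name under the package `extdata` directory; with no
#'   argument, lists the available files.
#' @export
bilff_extdata <- function(file = NULL) {
  d <- system.file("extdata", package = "bilff")
  if (is.null(file)) return(list.files(d))
  f <- file.path(d, file)
  if (!file.exists(f)) stop("no bundled file ", file)
  f
}
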