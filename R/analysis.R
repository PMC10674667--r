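# Trajectory analyses: RDF and peak metrics, coordination numbers, combined
# distance-angle distributions, spatial distribution functions, hydrogen-bond
# lifetimes, mean squared displacement / self-diffusion.
#
# Distances are reported in pm and times in ps, the conventions of the
# ionic-liquid hydrogen-bond literature; coordinates are Angstrom internally.

.traj_box <- function(traj, f) if (length(traj$box) >= f) traj$box[f] else traj$box[1]

#' Radial distribution function
#'
#' Shell-volume and ideal-density normalized histogram of minimum-image
#' distances between two selections, averaged over frames. The target number
#' density used in the normalization excludes, per observer, the self pair
#' and (with `exclude_intra`) targets in the same molecule, so a homogeneous
#' ideal gas gives g(r) = 1 exactly in expectation.
#'
#' @param traj a `bilff_trajectory`.
#' @param sel_a,sel_b observer / target atom index vectors (see
#'   [select_atoms()]).
#' @param bin_width histogram bin width, pm (default 1 pm).
#' @param r_max histogram range, pm; default (and maximum) half the smallest
#'   box edge.
#' @param exclude_intra drop pairs within the same molecule.
#' @param frames frame indices to include (default all).
#' @return `bilff_rdf`: data frame with `r` (pm, bin centers) and `g`, with
#'   attributes `rho` (target density, A^-3), `n_frames`, `counts`.
#' @export
rdf <- function(traj, sel_a, sel_b, bin_width = 1, r_max = NULL,
                exclude_intra = TRUE, frames = NULL) {
  stopifnot(length(sel_a) > 0, length(sel_b) > 0)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  boxes <- vapply(frames, function(f) .traj_box(traj, f), numeric(1))
  periodic <- any(boxes > 0)
  if (periodic) {
    half_min <- min(boxes[boxes > 0]) / 2 * 100   # pm
    if (is.null(r_max)) r_max <- half_min
    if (r_max > half_min + 1e-9)
      stop(sprintf("r_max (%.0f pm) exceeds half the smallest box edge (%.0f pm)",
                   r_max, half_min))
  } else if (is.null(r_max)) {
    stop("r_max is required for a non-periodic trajectory")
  }
  nbins <- ceiling(r_max / bin_width)
  mol <- traj$topology$atoms$mol_id
  counts <- numeric(nbins)
  vol <- 0
  for (f in frames) {
    p <- frame_pos(traj, f)
    counts <- counts + cpp_bin_distances(p, .traj_box(traj, f), sel_a, sel_b,
                                         mol, exclude_intra,
                                         bin_width / 100, nbins)
    vol <- vol + .traj_box(traj, f)^3
  }
  nf <- length(frames)
  # non-periodic (cluster) input: normalize to the analysis sphere instead of
  # the box, so g carries relative structure but does not tend to 1
  vol <- if (periodic) vol / nf else 4 / 3 * pi * (r_max / 100)^3
  # per-observer accessible target count
  excl <- vapply(sel_a, function(i) {
    same <- sel_b == i
    if (exclude_intra) same <- same | (mol[sel_b] == mol[i])
    sum(same)
  }, numeric(1))
  n_eff <- length(sel_b) - mean(excl)
  rho <- n_eff / vol                               # A^-3
  edges <- (0:nbins) * bin_width / 100             # A
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  ideal <- nf * length(sel_a) * rho * shell
  g <- ifelse(ideal > 0, counts / ideal, 0)
  out <- data.frame(r = (seq_len(nbins) - 0.5) * bin_width, g = g)
  structure(out, class = c("bilff_rdf", "data.frame"),
            rho = rho, n_frames = nf, counts = counts,
            n_obs = length(sel_a), volume = vol)
}

#' First peak (and following minimum) of an RDF
#'
#' Locates the first local maximum of the (optionally smoothed) curve and
#' the first local minimum after it, the integration bound conventionally
#' used for coordination numbers.
#'
#' @param x a `bilff_rdf`.
#' @param smooth odd running-mean window in bins (default 3; 1 disables).
#' @param min_height minimum g value for a maximum to count as a peak.
#' @return list with `r_peak`, `g_peak`, `r_min`, `g_min` (pm / dimensionless);
#'   `r_min` is `NA` if the curve does not turn up again within range.
#' @export
first_peak <- function(x, smooth = 3, min_height = 0.5) {
  g <- x$g
  n <- length(g)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    g <- stats::filter(g, k, sides = 2)
    g[is.na(g)] <- x$g[is.na(g)]
    g <- as.numeric(g)
  }
  w <- max(2, smooth)
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - w); hi <- min(n, i + w)
    g[i] >= max(g[lo:hi]) && g[i] > min_height &&
      i > lo && i < hi   # interior of its window
  }, logical(1))
  pk <- which(is_peak)
  if (!length(pk)) stop("no peak found: curve has no local maximum above min_height")
  p <- pk[1]
  # first local minimum after the peak
  mn <- NA_integer_
  for (i in (p + 1):max(p + 1, n - 1)) {
    if (i >= n) break
    lo <- max(p, i - w); hi <- min(n, i + w)
    if (g[i] <= min(g[lo:hi]) && i > lo && i < hi) { mn <- i; break }
  }
  list(r_peak = x$r[p], g_peak = g[p],
       r_min = if (is.na(mn)) NA_real_ else x$r[mn],
       g_min = if (is.na(mn)) NA_real_ else g[mn])
}

#' Coordination number from an RDF
#'
#' `n = 4 pi rho int_0^r g(r) r^2 dr` with `rho` the target number density
#' stored in the RDF; the upper bound is conventionally the first RDF
#' minimum.
#'
#' @param x a `bilff_rdf`.
#' @param r_upper integration bound, pm.
#' @return coordination number (dimensionless).
#' @export
coordination_number <- function(x, r_upper) {
  stopifnot(r_upper > 0, r_upper <= max(x$r) + 1)
  rho <- attr(x, "rho")
  r <- x$r / 100                       # A
  keep <- x$r <= r_upper
  f <- x$g[keep] * r[keep]^2
  dr <- diff(r[1:2])
  4 * pi * rho * sum(f) * dr
}

#' Combined distance-angle distribution function
#'
#' 2D histogram over the H...acceptor distance and the deviation from
#' linearity of the donor-H...acceptor arrangement (angle between the
#' donor-to-H and H-to-acceptor vectors; 0 deg = linear hydrogen bond).
#'
#' @param traj a `bilff_trajectory`.
#' @param don,hyd donor heavy atoms and their hydrogens (parallel index
#'   vectors, one donor per hydrogen).
#' @param acc acceptor atom indices.
#' @param r_max distance range, pm.
#' @param r_bin,a_bin bin widths (pm / deg).
#' @param frames frame indices (default all).
#' @return `bilff_cdf`: list with `r` (pm), `angle` (deg) bin centers and
#'   `counts` matrix (distance x angle).
#' @export
cdf_distance_angle <- function(traj, don, hyd, acc, r_max = 800,
                               r_bin = 10, a_bin = 2, frames = NULL) {
  stopifnot(length(don) == length(hyd), length(hyd) > 0, length(acc) > 0)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nr <- ceiling(r_max / r_bin); na_ <- ceiling(180 / a_bin)
  counts <- matrix(0, nr, na_)
  mol <- traj$topology$atoms$mol_id
  for (f in frames) {
    p <- frame_pos(traj, f)
    L <- .traj_box(traj, f)
    for (h in seq_along(hyd)) {
      ih <- hyd[h]; id <- don[h]
      ok <- acc != ih & acc != id & mol[acc] != mol[ih]
      if (!any(ok)) next
      d <- sweep(p[acc[ok], , drop = FALSE], 2, p[ih, ])
      if (L > 0) d <- d - L * round(d / L)
      r <- sqrt(rowSums(d^2))
      u <- p[ih, ] - p[id, ]
      if (L > 0) u <- u - L * round(u / L)
      un <- sqrt(sum(u^2))
      ca <- pmin(1, pmax(-1, (d %*% u)[, 1] / (r * un)))
      ang <- acos(ca) * 180 / pi
      ri <- floor(r * 100 / r_bin) + 1
      ai <- pmin(na_, floor(ang / a_bin) + 1)
      keep <- ri >= 1 & ri <= nr
      for (k in which(keep)) counts[ri[k], ai[k]] <- counts[ri[k], ai[k]] + 1
    }
  }
  structure(list(r = (seq_len(nr) - 0.5) * r_bin,
                 angle = (seq_len(na_) - 0.5) * a_bin,
                 counts = counts, n_frames = length(frames)),
            class = "bilff_cdf")
}

# orthonormal molecule-fixed frame from three anchor positions
.anchor_frame <- function(a1, a2, a3) {
  ex <- a2 - a1
  nx <- sqrt(sum(ex^2))
  v <- a3 - a1
  ez <- c(ex[2] * v[3] - ex[3] * v[2],
          ex[3] * v[1] - ex[1] * v[3],
          ex[1] * v[2] - ex[2] * v[1])
  nz <- sqrt(sum(ez^2))
  if (nx < 1e-8 || nz < 1e-8) stop("collinear anchor atoms")
  ex <- ex / nx; ez <- ez / nz
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  rbind(ex, ey, ez)
}

#' Spatial distribution function
#'
#' Number density of target atoms in the molecule-fixed frame defined by
#' three anchor atoms of each reference molecule (anchor 1 is the origin,
#' anchor 2 defines +x, anchor 3 the xy half-plane).
#'
#' @param traj a `bilff_trajectory`.
#' @param anchor_species reference species name.
#' @param anchor_labels length-3 vector of atom labels within the reference
#'   template.
#' @param target target atom indices.
#' @param extent half-width of the cubic grid, pm.
#' @param resolution voxel edge, pm.
#' @param frames frame indices (default all).
#' @return `bilff_sdf`: list with `axes` (pm bin centers) and `density`
#'   (3D array, nm^-3).
#' @export
sdf <- function(traj, anchor_species, anchor_labels, target,
                extent = 600, resolution = 50, frames = NULL) {
  stopifnot(length(anchor_labels) == 3, length(target) > 0)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  a <- traj$topology$atoms
  nb <- ceiling(2 * extent / resolution)
  dens <- array(0, c(nb, nb, nb))
  mols <- unique(a$mol_id[a$species == anchor_species])
  if (!length(mols)) stop("no molecules of species ", anchor_species)
  anchors <- lapply(mols, function(m) {
    idx <- vapply(anchor_labels, function(lb)
      which(a$mol_id == m & a$label == lb)[1], integer(1))
    if (anyNA(idx)) stop("anchor label not found in species ", anchor_species)
    idx
  })
  ext_a <- extent / 100; res_a <- resolution / 100
  for (f in frames) {
    p <- frame_pos(traj, f)
    L <- .traj_box(traj, f)
    for (anc in anchors) {
      R <- .anchor_frame(p[anc[1], ], p[anc[2], ], p[anc[3], ])
      d <- sweep(p[target, , drop = FALSE], 2, p[anc[1], ])
      if (L > 0) d <- d - L * round(d / L)
      loc <- d %*% t(R)
      ix <- floor((loc[, 1] + ext_a) / res_a) + 1
      iy <- floor((loc[, 2] + ext_a) / res_a) + 1
      iz <- floor((loc[, 3] + ext_a) / res_a) + 1
      keep <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb & iz >= 1 & iz <= nb
      for (k in which(keep))
        dens[ix[k], iy[k], iz[k]] <- dens[ix[k], iy[k], iz[k]] + 1
    }
  }
  vox_nm3 <- (res_a / 10)^3
  dens <- dens / (length(frames) * length(anchors) * vox_nm3)
  ax <- ((seq_len(nb) - 0.5) * resolution) - extent
  structure(list(axes = ax, density = dens, n_frames = length(frames),
                 n_ref = length(anchors), resolution = resolution),
            class = "bilff_sdf")
}

#' Hydrogen-bond criterion
#'
#' Geometric criterion: H...acceptor distance below `rmax` and deviation
#' from donor-H...acceptor linearity below `alpha_max`. Defaults bracket the
#' first peak of the distance-angle distribution of strong ionic hydrogen
#' bonds.
#'
#' @param rmax distance cutoff, pm.
#' @param alpha_max angular cutoff, deg.
#' @export
hbond_criterion <- function(rmax = 300, alpha_max = 30) {
  stopifnot(rmax > 0, alpha_max > 0, alpha_max <= 90)
  structure(list(rmax = rmax, alpha_max = alpha_max), class = "bilff_hbond_criterion")
}

#' Derive a hydrogen-bond criterion from the trajectory's own distributions
#'
#' Follows the standard construction used in force-field validation work:
#' the distance cutoff is the first minimum of the H...acceptor RDF (the
#' bound that also delimits the coordination integral) and the angular
#' cutoff is the smallest angle containing `angle_mass` of the
#' close-contact angular distribution, i.e. the rectangle bracketing the
#' first peak of the combined distance-angle distribution.
#'
#' @param traj a `bilff_trajectory`.
#' @param don,hyd,acc donor / hydrogen / acceptor index vectors.
#' @param angle_mass fraction of the close-contact angular mass to bracket.
#' @param frames frame indices (default all).
#' @param r_max range of the underlying RDF, pm.
#' @return a [hbond_criterion()].
#' @export
derive_hbond_criterion <- function(traj, don, hyd, acc, angle_mass = 0.9,
                                   frames = NULL, r_max = 600) {
  g <- rdf(traj, hyd, acc, bin_width = 5, r_max = r_max, frames = frames)
  pk <- first_peak(g, smooth = 3, min_height = 1)
  rmax <- if (is.na(pk$r_min)) 350 else pk$r_min
  cd <- cdf_distance_angle(traj, don, hyd, acc, r_max = rmax, r_bin = rmax,
                           a_bin = 5, frames = frames)
  adist <- colSums(cd$counts)
  cum <- cumsum(adist) / sum(adist)
  amax <- cd$angle[which(cum >= angle_mass)[1]] + 2.5
  hbond_criterion(rmax = rmax, alpha_max = min(90, amax))
}

# exponential tail estimate: integrate sampled curve and extend beyond the
# window with a log-linear fit over the last portion of the decay
.tau_integral <- function(t, C, fit_frac = 0.5) {
  dt <- diff(t[1:2])
  base <- (sum(C) - (C[1] + C[length(C)]) / 2) * dt   # trapezoid
  i0 <- max(2, ceiling(length(C) * (1 - fit_frac)))
  idx <- seq(i0, length(C))
  idx <- idx[C[idx] > 1e-6]
  censored <- FALSE
  tail <- 0
  if (length(idx) >= 5) {
    fit <- stats::lm(log(C[idx]) ~ t[idx])
    slope <- unname(coef(fit)[2])
    if (is.finite(slope) && slope < -1e-9 && -1 / slope <= 100 * max(t)) {
      tau_fit <- -1 / slope
      tail <- C[length(C)] * tau_fit
    } else censored <- TRUE   # no decay (or only a plateau) within the window
  } else if (C[length(C)] > 1e-6) censored <- TRUE
  list(tau = base + tail, censored = censored)
}

#' Hydrogen-bond lifetimes (intermittent and continuous)
#'
#' Builds the per-pair bond indicator h(t) under the geometric criterion and
#' derives: the intermittent lifetime from the normalized autocorrelation
#' `C(t) = <h(0) h(t)> / <h>` (re-formation allowed), and the continuous
#' lifetime from the survival probability `S(t)` of an uninterrupted bond
#' (time to first breakage), both integrated with a single-exponential tail
#' extension beyond the sampled window. Pairs that stay bonded for the whole
#' window make the estimate a lower bound; this censoring is flagged.
#'
#' @param traj a `bilff_trajectory` with evenly spaced frames.
#' @param don,hyd,acc donor / hydrogen / acceptor index vectors (donors
#'   parallel to hydrogens).
#' @param criterion a [hbond_criterion()].
#' @param frames frame indices (default all).
#' @return `bilff_lifetime`: list with `tau_intermittent`, `tau_continuous`
#'   (ps), `curves` (data frame t_ps / intermittent / continuous),
#'   `censored` flags and bookkeeping counts.
#' @export
hbond_lifetimes <- function(traj, don, hyd, acc,
                            criterion = hbond_criterion(), frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nt <- length(frames)
  stopifnot(nt >= 4)
  dtf <- diff(traj$time[frames])
  if (max(abs(dtf - dtf[1])) > 1e-6 * dtf[1]) stop("frames must be evenly spaced")
  dt_ps <- dtf[1] / 1000
  mol <- traj$topology$atoms$mol_id
  np <- length(hyd) * length(acc)
  H <- matrix(FALSE, nt, np)
  for (k in seq_len(nt)) {
    p <- frame_pos(traj, frames[k])
    ind <- cpp_hbond_indicator(p, .traj_box(traj, frames[k]), don, hyd, acc,
                               mol, criterion$rmax / 100, criterion$alpha_max)
    H[k, ] <- as.vector(ind)
  }
  n_on <- sum(H)
  if (n_on == 0) stop("no hydrogen bonds ever formed under this criterion; ",
                      "lifetimes are undefined")
  ever <- colSums(H) > 0
  H <- H[, ever, drop = FALSE]

  # intermittent: FFT autocorrelation per pair, summed
  nlag <- nt %/% 2
  m <- 2^ceiling(log2(2 * nt))
  Hp <- rbind(H * 1, matrix(0, m - nt, ncol(H)))
  F_ <- stats::mvfft(Hp)
  ac <- Re(stats::mvfft(F_ * Conj(F_), inverse = TRUE))[seq_len(nlag + 1), ,
                                                        drop = FALSE] / m
  norm <- nt - 0:nlag                     # origins per lag
  Craw <- rowSums(ac) / norm
  C <- Craw / Craw[1]

  # continuous: survival from run lengths; origins whose lag-l observation
  # would fall beyond the trajectory are censored out of the denominator
  runs <- do.call(rbind, lapply(seq_len(ncol(H)), function(j) {
    r <- rle(H[, j])
    start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    cbind(start = start[r$values], len = r$lengths[r$values])
  }))
  S <- vapply(0:nlag, function(l) {
    num <- sum(pmax(0, runs[, "len"] - l))
    den <- sum(pmax(0, pmin(runs[, "len"], nt - l - runs[, "start"] + 1)))
    if (den > 0) num / den else 0
  }, numeric(1))
  S <- S / S[1]

  t_ps <- (0:nlag) * dt_ps
  ti <- .tau_integral(t_ps, C)
  tc <- .tau_integral(t_ps, S)
  structure(list(
    tau_intermittent = ti$tau, tau_continuous = tc$tau,
    curves = data.frame(t_ps = t_ps, intermittent = C, continuous = S),
    censored = c(intermittent = ti$censored, continuous = tc$censored),
    n_pairs = ncol(H), n_on = n_on, dt_ps = dt_ps,
    criterion = criterion
  ), class = "bilff_lifetime")
}

#' @export
print.bilff_lifetime <- function(x, ...) {
  cat(sprintf("hydrogen-bond lifetimes (criterion: r <= %.0f pm, angle <= %.0f deg)\n",
              x$criterion$rmax, x$criterion$alpha_max))
  cat(sprintf("  intermittent tau = %.2f ps%s\n", x$tau_intermittent,
              if (x$censored["intermittent"]) " (censored: no decay in window)" else ""))
  cat(sprintf("  continuous   tau = %.2f ps%s\n", x$tau_continuous,
              if (x$censored["continuous"]) " (censored: no decay in window)" else ""))
  invisible(x)
}

#' Mean squared displacement and self-diffusion coefficient
#'
#' Einstein relation `D = slope(MSD) / 6` with the MSD averaged over all
#' time origins and the selected atoms; coordinates must be unwrapped (the
#' MD engine stores unwrapped positions).
#'
#' @param traj a `bilff_trajectory`.
#' @param sel atom indices.
#' @param max_lag_frac largest lag as a fraction of the trajectory length.
#' @param fit_window fractions of the maximum lag used for the linear fit
#'   (default 10--50%, where time origins are well sampled).
#' @param frames frame indices (default all).
#' @return `bilff_msd`: list with `msd` (data frame t_ps / msd_pm2), `D` in
#'   1e-11 m^2 s^-1, fit `r_squared` and the fit window (ps).
#' @export
diffusion <- function(traj, sel, max_lag_frac = 0.5,
                      fit_window = c(0.1, 0.5), frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nt <- length(frames)
  stopifnot(nt >= 8, length(sel) > 0)
  dt_ps <- diff(traj$time[frames][1:2]) / 1000
  nlag <- max(4, floor(nt * max_lag_frac))
  # coordinate array (nt x natoms x 3)
  X <- traj$frames[frames, , drop = FALSE]
  cols <- as.vector(rbind(3 * (sel - 1) + 1, 3 * (sel - 1) + 2, 3 * (sel - 1) + 3))
  X <- X[, cols, drop = FALSE]
  msd <- numeric(nlag)
  for (l in seq_len(nlag)) {
    d <- X[(1 + l):nt, , drop = FALSE] - X[1:(nt - l), , drop = FALSE]
    msd[l] <- sum(d^2) / ((nt - l) * length(sel))
  }
  t_ps <- seq_len(nlag) * dt_ps
  msd_pm2 <- msd * 1e4                     # A^2 -> pm^2
  w <- t_ps >= fit_window[1] * max(t_ps) & t_ps <= fit_window[2] * max(t_ps)
  fit <- stats::lm(msd_pm2[w] ~ t_ps[w])
  slope <- coef(fit)[2]                    # pm^2 / ps
  r2 <- summary(fit)$r.squared
  D <- slope / 6 * 0.1                     # 1e-11 m^2/s
  if (!is.finite(D)) D <- 0
  structure(list(msd = data.frame(t_ps = t_ps, msd_pm2 = msd_pm2),
                 D = unname(max(0, D)), r_squared = r2,
                 window_ps = range(t_ps[w])),
            class = "bilff_msd")
}

#' @export
print.bilff_msd <- function(x, ...) {
  cat(sprintf("self-diffusion: D = %.3f x 1e-11 m^2/s (fit window %.1f-%.1f ps, R^2 = %.4f)\n",
              x$D, x$window_ps[1], x$window_ps[2], x$r_squared))
  invisible(x)
}
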