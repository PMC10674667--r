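# Seeded synthetic trajectory generators with known statistical structure.
# They make every analysis operation testable without running any MD.

#' Specify a synthetic fixture trajectory
#'
#' Supported generators:
#' \describe{
#'   \item{ideal_gas}{`n` non-interacting points re-drawn uniformly in the
#'     box every frame; g(r) = 1, voxel counts Poisson.}
#'   \item{frozen_pair}{two atoms at fixed separation `d` (pm); the RDF is a
#'     single occupied bin.}
#'   \item{telegraph_hbond}{`n_pairs` donor-H/acceptor triples whose
#'     acceptor hops between a bonded (200 pm, linear) and an unbonded
#'     (600 pm) position as a two-state Markov chain with rates `k_on`,
#'     `k_off` (1/ps); continuous lifetime 1/k_off.}
#'   \item{brownian}{`n` independent random walkers with diffusion
#'     coefficient `D` (1e-11 m^2/s).}
#'   \item{gaussian_shell}{`n_t` targets per frame at Gaussian-distributed
#'     radius (`r0`, `sd`, pm) around a fixed center, over a uniform
#'     background of `n_bg` points; RDF peak at r0.}
#' }
#'
#' @param kind generator name.
#' @param frames number of frames.
#' @param dt frame spacing, fs.
#' @param box cubic box edge, pm (0 = non-periodic).
#' @param seed integer seed.
#' @param ... generator parameters (see above).
#' @return `bilff_fixture_spec`.
#' @export
fixture_spec <- function(kind = c("ideal_gas", "frozen_pair", "telegraph_hbond",
                                  "brownian", "gaussian_shell"),
                         frames = 100, dt = 1000, box = 2000, seed = 1, ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  defaults <- switch(kind,
    ideal_gas = list(n = 200),
    frozen_pair = list(d = 300),
    telegraph_hbond = list(n_pairs = 50, k_on = 0.5, k_off = 0.5),
    brownian = list(n = 50, D = 20),
    gaussian_shell = list(n_t = 20, r0 = 200, sd = 15, n_bg = 0))
  bad <- setdiff(names(pars), names(defaults))
  if (length(bad)) stop("invalid parameter(s) for ", kind, ": ",
                        paste(bad, collapse = ", "))
  pars <- utils::modifyList(defaults, pars)
  if (frames < 1 || dt <= 0 || box < 0) stop("invalid fixture geometry")
  structure(list(kind = kind, frames = as.integer(frames), dt = dt,
                 box = box, seed = seed, pars = pars),
            class = "bilff_fixture_spec")
}

.as_traj <- function(sys, frames_mat, dt_fs, box_a) {
  structure(list(
    topology = sys, frames = frames_mat,
    time = (seq_len(nrow(frames_mat)) - 1) * dt_fs,
    box = rep(box_a, nrow(frames_mat)),
    temperature = rep(NA_real_, nrow(frames_mat)),
    pressure = rep(NA_real_, nrow(frames_mat)),
    epot = rep(NA_real_, nrow(frames_mat)),
    ekin = rep(NA_real_, nrow(frames_mat)),
    final = list(pos = matrix(frames_mat[nrow(frames_mat), ], ncol = 3,
                              byrow = TRUE),
                 vel = NULL, box = box_a)
  ), class = "bilff_trajectory")
}

#' Generate a synthetic fixture trajectory
#'
#' Deterministic for a given spec (the seed is part of the spec).
#'
#' @param spec a [fixture_spec()].
#' @return `bilff_trajectory`; generator-specific metadata is attached as
#'   attributes (e.g. `pairs` and `rates` for `telegraph_hbond`, `D_pm2_ps`
#'   for `brownian`).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "bilff_fixture_spec"))
  set.seed(spec$seed)
  L <- spec$box / 100          # Angstrom
  nf <- spec$frames
  p <- spec$pars
  switch(spec$kind,
    ideal_gas = {
      n <- p$n
      fm <- matrix(runif(nf * 3 * n, 0, L), nrow = nf)
      sys <- raw_system(matrix(fm[1, ], ncol = 3, byrow = TRUE), box = L)
      .as_traj(sys, fm, spec$dt, L)
    },
    frozen_pair = {
      d <- p$d / 100
      pos <- rbind(c(L / 2, L / 2, L / 2), c(L / 2 + d, L / 2, L / 2))
      fm <- matrix(rep(as.vector(t(pos)), nf), nrow = nf, byrow = TRUE)
      sys <- raw_system(pos, box = L)
      .as_traj(sys, fm, spec$dt, L)
    },
    telegraph_hbond = {
      npair <- p$n_pairs
      dt_ps <- spec$dt / 1000
      p_on <- 1 - exp(-p$k_on * dt_ps)    # off -> on per frame
      p_off <- 1 - exp(-p$k_off * dt_ps)  # on -> off per frame
      # states over time (start bonded so runs begin immediately)
      state <- matrix(FALSE, nf, npair)
      state[1, ] <- TRUE
      for (k in 2:nf) {
        u <- runif(npair)
        state[k, ] <- ifelse(state[k - 1, ], u > p_off, u < p_on)
      }
      # donor at y-offset, H +1 A in x, acceptor at 2 A (on) or 6 A (off)
      n <- 3 * npair
      fm <- matrix(0, nf, 3 * n)
      ybase <- (seq_len(npair) - 1) * 20
      for (k in seq_len(nf)) {
        pos <- matrix(0, n, 3)
        for (j in seq_len(npair)) {
          o <- 3 * (j - 1)
          pos[o + 1, ] <- c(0, ybase[j], 0)
          pos[o + 2, ] <- c(1, ybase[j], 0)
          pos[o + 3, ] <- c(1 + if (state[k, j]) 2 else 6, ybase[j], 0)
        }
        fm[k, ] <- as.vector(t(pos))
      }
      mol <- as.vector(t(cbind(seq_len(npair) * 2 - 1, seq_len(npair) * 2 - 1,
                               seq_len(npair) * 2)))
      sys <- raw_system(matrix(fm[1, ], ncol = 3, byrow = TRUE), box = 0,
                        mol_id = mol)
      tr <- .as_traj(sys, fm, spec$dt, 0)
      idx <- seq_len(npair)
      attr(tr, "pairs") <- list(don = 3 * (idx - 1) + 1, hyd = 3 * (idx - 1) + 2,
                                acc = 3 * (idx - 1) + 3)
      attr(tr, "rates") <- c(k_on = p$k_on, k_off = p$k_off)
      attr(tr, "states") <- state
      tr
    },
    brownian = {
      n <- p$n
      D_pm2_ps <- p$D * 10                # 1e-11 m^2/s -> pm^2/ps
      dt_ps <- spec$dt / 1000
      sd_a <- sqrt(2 * D_pm2_ps * dt_ps) / 100
      fm <- matrix(0, nf, 3 * n)
      fm[1, ] <- runif(3 * n, 0, max(L, 10))
      for (k in 2:nf) fm[k, ] <- fm[k - 1, ] + rnorm(3 * n, 0, sd_a)
      sys <- raw_system(matrix(fm[1, ], ncol = 3, byrow = TRUE), box = 0)
      tr <- .as_traj(sys, fm, spec$dt, 0)
      attr(tr, "D_pm2_ps") <- D_pm2_ps
      tr
    },
    gaussian_shell = {
      nt <- p$n_t; nbg <- p$n_bg
      n <- 1 + nt + nbg
      ctr <- rep(L / 2, 3)
      fm <- matrix(0, nf, 3 * n)
      for (k in seq_len(nf)) {
        u <- matrix(rnorm(3 * nt), nt, 3)
        u <- u / sqrt(rowSums(u^2))
        r <- abs(rnorm(nt, p$r0, p$sd)) / 100
        tgt <- sweep(u * r, 2, ctr, `+`)
        bg <- if (nbg > 0) matrix(runif(3 * nbg, 0, L), nbg, 3) else
          matrix(0, 0, 3)
        fm[k, ] <- as.vector(t(rbind(ctr, tgt, bg)))
      }
      sys <- raw_system(matrix(fm[1, ], ncol = 3, byrow = TRUE), box = L)
      .as_traj(sys, fm, spec$dt, L)
    }
  )
}
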