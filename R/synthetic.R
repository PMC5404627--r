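#' Parameters of the synthetic pore-formation trajectory
#'
#' The generator emulates the phenomenology of bilayer electroporation at the
#' coarse-grained level the analysis sees: two quasi-planar leaflets of
#' representative sites on jittered square lattices in a periodic
#' orthorhombic box (defaults: 64 sites per leaflet, ~70 x 70 x 120 Angstrom
#' box, 10 ps stride, 500 frames), a pore that opens at a set onset frame by
#' pushing the pore-lining sites radially outward, and the accompanying NPT
#' box deformation (z compresses, x/y elongate at constant volume). It is a
#' geometric fixture with exact ground truth, not an MD engine.
#'
#' @param n_per_leaflet sites per leaflet; must be a perfect square.
#' @param box0 initial box edge lengths, Angstrom.
#' @param leaflet_offset leaflet plane offset from the box z-centre, Angstrom.
#' @param jitter_sigma rms magnitude of the per-frame in-plane thermal
#'   displacement vector, Angstrom (stationary vibration about lattice
#'   anchors, not cumulative diffusion).
#' @param n_frames,dt frame count and spacing (ps).
#' @param pore_onset_frame 0-based frame at which the pore starts opening.
#' @param pore_center in-plane pore centre (defaults to the box centre).
#' @param pore_radius sites within this distance of the centre at onset are
#'   pore-lining, Angstrom.
#' @param pore_push radial displacement per frame during opening, Angstrom.
#' @param opening_frames duration of the radial push, frames.
#' @param box_shrink_rate z shrinkage per frame after onset, Angstrom; x and
#'   y grow to conserve box volume.
#' @param distractor if `TRUE`, one random non-pore site is displaced far
#'   from its anchor before onset (an outlier not associated with the pore).
#' @param seed RNG seed; same seed, same parameters: bitwise-identical output.
#' @return A `PoreSimParams` list.
#' @export
pore_sim_params <- function(n_per_leaflet = 64, box0 = c(70, 70, 120),
                            leaflet_offset = 20, jitter_sigma = 0.3,
                            n_frames = 500, dt = 10, pore_onset_frame = 300,
                            pore_center = NULL, pore_radius = 12,
                            pore_push = 0.5, opening_frames = 50,
                            box_shrink_rate = 0.08, distractor = FALSE,
                            seed = 1) {
  nx <- round(sqrt(n_per_leaflet))
  if (nx * nx != n_per_leaflet)
    stop("parameter error: n_per_leaflet must be a perfect square")
  if (!(pore_onset_frame >= 1 && pore_onset_frame < n_frames))
    stop("parameter error: need 1 <= pore_onset_frame < n_frames")
  if (is.null(pore_center)) pore_center <- box0[1:2] / 2
  if (pore_radius >= min(box0[1:2]) / 2)
    stop("parameter error: pore_radius must be < min(box x, y)/2")
  if (any(box0 <= 0) || jitter_sigma < 0 || dt <= 0 || pore_push < 0 ||
      box_shrink_rate < 0 || opening_frames < 1)
    stop("parameter error: invalid PoreSimParams")
  if (box0[3] - box_shrink_rate * (n_frames - 1 - pore_onset_frame) <= 0)
    stop("parameter error: box z would shrink to zero before the last frame")
  structure(list(n_per_leaflet = n_per_leaflet, box0 = box0,
                 leaflet_offset = leaflet_offset, jitter_sigma = jitter_sigma,
                 n_frames = n_frames, dt = dt,
                 pore_onset_frame = pore_onset_frame,
                 pore_center = pore_center, pore_radius = pore_radius,
                 pore_push = pore_push, opening_frames = opening_frames,
                 box_shrink_rate = box_shrink_rate, distractor = distractor,
                 seed = seed), class = "PoreSimParams")
}

#' Generate a synthetic pore-formation trajectory with ground truth
#'
#' Sites vibrate about two jittered square lattices (in-plane Gaussian
#' jitter, wrapped periodically); from the onset frame the sites found within
#' `pore_radius` of the pore centre are pushed radially outward for
#' `opening_frames` frames, breaking their contacts, while the box follows a
#' linear volume-conserving deformation schedule (z down, x/y up) applied
#' affinely to the site coordinates, as an NPT barostat rescales positions.
#'
#' @param params a [pore_sim_params()].
#' @return A list with `traj` (a [frame_series()]) and `truth` (a
#'   `GroundTruth` list: `pore_lining_ids` as residue ids, `onset_time` ps,
#'   `distractor_id` or NA, `seed`, `params`).
#' @export
make_pore_trajectory <- function(params = pore_sim_params()) {
  stopifnot(inherits(params, "PoreSimParams"))
  set.seed(params$seed)
  p <- params
  nx <- round(sqrt(p$n_per_leaflet))
  ns <- 2L * p$n_per_leaflet
  nf <- p$n_frames
  sax <- p$jitter_sigma / sqrt(2)  # per-axis sd of the 2D jitter vector

  # fractional lattice anchors, jittered once (leaflet A then leaflet B)
  g <- (seq_len(nx) - 0.5) / nx
  lat <- as.matrix(expand.grid(x = g, y = g))
  anchor_frac <- rbind(lat, lat) +
    matrix(rnorm(2L * ns, sd = sax), ns, 2) / rep(p$box0[1:2], each = ns)
  anchor_frac <- anchor_frac %% 1
  zfrac <- rep(c((p$box0[3] / 2 - p$leaflet_offset) / p$box0[3],
                 (p$box0[3] / 2 + p$leaflet_offset) / p$box0[3]),
               each = p$n_per_leaflet)

  # per-frame thermal jitter, drawn in one block for determinism
  jit <- array(rnorm(nf * ns * 2L, sd = sax), c(nf, ns, 2L))

  # deformation schedule (frame index 0-based; shrink starts after onset)
  f0 <- seq_len(nf) - 1L
  bz <- p$box0[3] - p$box_shrink_rate * pmax(0L, f0 - p$pore_onset_frame)
  sxy <- sqrt(p$box0[3] / bz)  # volume-conserving in-plane scale factor
  box <- cbind(p$box0[1] * sxy, p$box0[2] * sxy, bz)

  coords <- array(0, c(nf, ns, 3))
  for (ax in 1:2)
    coords[, , ax] <- outer(box[, ax], anchor_frac[, ax]) + jit[, , ax]
  coords[, , 3] <- outer(bz, zfrac)

  # ground truth: sites within pore_radius of the centre at the onset frame
  ko <- p$pore_onset_frame + 1L
  dc <- cbind(coords[ko, , 1] - p$pore_center[1],
              coords[ko, , 2] - p$pore_center[2])
  dc <- wrap_disp(dc, rep(box[ko, 1:2], each = ns))
  rad <- sqrt(rowSums(dc^2))
  lining <- which(rad <= p$pore_radius)

  # radial push of the pore-lining sites during the opening phase
  if (length(lining) > 0 && p$pore_push > 0) {
    u <- dc[lining, , drop = FALSE] / pmax(rad[lining], 1e-9)
    off <- p$pore_push * pmin(pmax(f0 - p$pore_onset_frame, 0L),
                              p$opening_frames)
    for (ax in 1:2)
      coords[, lining, ax] <- coords[, lining, ax] +
        outer(off, u[, ax])
  }

  distractor_id <- NA_integer_
  if (isTRUE(p$distractor)) {
    cand <- setdiff(seq_len(ns), lining)
    distractor_id <- cand[sample.int(length(cand), 1L)]
    theta <- stats::runif(1, 0, 2 * pi)
    kd <- max(1L, floor(p$pore_onset_frame / 2)) + 1L
    shift <- 20 * c(cos(theta), sin(theta))
    for (ax in 1:2)
      coords[kd:nf, distractor_id, ax] <-
        coords[kd:nf, distractor_id, ax] + shift[ax]
  }

  for (ax in 1:3)  # wrap into each frame's own box
    coords[, , ax] <- coords[, , ax] %% box[, ax]

  meta <- data.frame(resid = seq_len(ns), resname = "LIP", atom = "P",
                     chain = rep(c("A", "B"), each = p$n_per_leaflet),
                     stringsAsFactors = FALSE)
  traj <- frame_series(times = f0 * p$dt, coords = coords, box = box,
                       site_meta = meta)
  truth <- structure(list(pore_lining_ids = meta$resid[lining],
                          onset_time = p$pore_onset_frame * p$dt,
                          distractor_id = distractor_id,
                          seed = p$seed, params = p),
                     class = "GroundTruth")
  if (length(truth$pore_lining_ids) == 0)
    warning("no pore-lining sites for these parameters")
  list(traj = traj, truth = truth)
}

#' Seeded bivariate Gaussian sample
#'
#' `n` draws from a standard bivariate normal with correlation `rho` — the
#' closed-form test bed for the mutual information estimator, for which
#' `I = -log(1 - rho^2) / 2` nats.
#'
#' @param n sample size (>= 2).
#' @param rho correlation, strictly inside (-1, 1).
#' @param seed RNG seed.
#' @return List with numeric vectors `x` and `y`.
#' @export
make_gaussian_pair <- function(n, rho, seed = 1) {
  if (n < 2) stop("parameter error: n must be >= 2")
  if (abs(rho) >= 1) stop("parameter error: |rho| must be < 1")
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Seeded zero-inflated activity fixture
#'
#' A contiguous leading block of `floor(zero_fraction * n)` exact zeros (a
#' quiescent period) followed by positive half-Gaussian samples — the
#' zero-valued-activity regime that uniform-bandwidth density estimators
#' handle poorly and the adaptive-bandwidth estimator must tolerate.
#'
#' @param n length of the series.
#' @param zero_fraction fraction of exact zeros, in `[0, 1)`.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`, `>= 0`.
#' @export
make_zero_inflated_activity <- function(n, zero_fraction = 0.5, seed = 1) {
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("parameter error: zero_fraction must be in [0, 1)")
  set.seed(seed)
  nz <- floor(zero_fraction * n)
  c(rep(0, nz), abs(rnorm(n - nz)))
}
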