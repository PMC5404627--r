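# Independent brute-force oracles, deliberately naive and separate from the
# implementation paths they check.

# minimum-image distance by enumerating the 27 nearest periodic images
# (both points wrapped into the primary cell first, as the convention requires)
oracle_min_image <- function(p, q, box) {
  p <- p %% box
  q <- q %% box
  best <- Inf
  for (nx in -1:1) for (ny in -1:1) for (nz in -1:1) {
    d <- p - q + box * c(nx, ny, nz)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# two-state hysteresis machine, written as an explicit frame loop
oracle_hysteresis <- function(d, lo, hi, times = seq_along(d) - 1) {
  state <- if (d[1] < lo) "PRESENT" else "ABSENT"
  out <- data.frame(frame = integer(), time = numeric(), kind = character())
  for (k in seq_along(d)[-1]) {
    if (state == "ABSENT" && d[k] < lo) {
      state <- "PRESENT"
      out <- rbind(out, data.frame(frame = k - 1, time = times[k],
                                   kind = "forming"))
    } else if (state == "PRESENT" && d[k] > hi) {
      state <- "ABSENT"
      out <- rbind(out, data.frame(frame = k - 1, time = times[k],
                                   kind = "breaking"))
    }
  }
  out
}

# single-cutoff event counter (no buffer) for the recrossing-suppression bound
oracle_single_cutoff_events <- function(d, cut) {
  present <- d < cut
  sum(diff(present) != 0)
}

# textbook Pearson via the direct covariance / sigma formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# masked row-mean compression
oracle_masked_rowmean <- function(R, mask) {
  sapply(seq_len(nrow(R)), function(i) {
    j <- which(mask[i, ])
    if (length(j) == 0) 0 else mean(R[i, j])
  })
}

# small hand-built FrameSeries
toy_frameseries <- function(coords_list, box, dt = 1,
                            resname = "LIP", atom = "P") {
  nf <- length(coords_list)
  ns <- nrow(coords_list[[1]])
  coords <- array(0, c(nf, ns, 3))
  for (k in seq_len(nf)) coords[k, , ] <- coords_list[[k]]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  frame_series(times = (seq_len(nf) - 1) * dt, coords = coords, box = box,
               site_meta = data.frame(resid = seq_len(ns), resname = resname,
                                      atom = atom, chain = "A"))
}

# a static trajectory of n sites at fixed positions
static_frameseries <- function(pos, box = c(100, 100, 100), nf = 3) {
  toy_frameseries(rep(list(pos), nf), matrix(box, nf, 3, byrow = TRUE))
}

# distance series wrapper for a single hand-made trace
toy_distance_series <- function(d, dt = 1) {
  structure(list(times = (seq_along(d) - 1) * dt, i = 1L, j = 2L,
                 d = matrix(d, ncol = 1)), class = "DistanceSeries")
}

# small default-shaped pore simulation for pipeline tests (fast)
small_pore_params <- function(seed = 1, ...) {
  pore_sim_params(n_per_leaflet = 36, box0 = c(52.5, 52.5, 120),
                  n_frames = 120, pore_onset_frame = 70, opening_frames = 25,
                  seed = seed, ...)
}
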