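#' Minimum-image distance in an orthorhombic periodic box
#'
#' Returns the shortest distance between `p` and `q` over all periodic images
#' of the cell. For an orthorhombic box this is the magnitude of the per-axis
#' wrapped displacement `delta - box * round(delta / box)`. R's `round()`
#' rounds half to even, so displacements of exactly half a box length (a
#' measure-zero tie) resolve by that convention.
#'
#' @param p,q numeric 3-vectors, Angstrom.
#' @param box numeric 3-vector of box edge lengths, Angstrom, all positive.
#' @return The minimum-image distance in Angstrom.
#' @export
min_image_distance <- function(p, q, box) {
  if (any(box <= 0) || any(!is.finite(box)))
    stop("domain error: box components must be positive and finite")
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# wrapped displacement for matrices of displacements (frames/pairs x 3),
# box recycled rowwise
wrap_disp <- function(d, box) d - box * round(d / box)

#' Pairs of sites with at least one significant interaction
#'
#' Builds the set of site pairs (i < j, 1-based) whose minimum-image distance
#' comes within `cutoff` in at least one frame of the trajectory window
#' ("ever within cutoff"), or all C(n,2) pairs when `cutoff` is `NULL`/`Inf`.
#' A 15 Angstrom cutoff is the customary choice for culling solvent-scale
#' systems down to significant interactions. The sweep is streaming over
#' frames (one per-pair flag), so memory is O(pairs), not O(pairs x frames).
#'
#' @param traj a [frame_series()].
#' @param cutoff cull distance in Angstrom, or `NULL` for all pairs.
#' @return A `PairSet`: list with integer vectors `i`, `j` (ascending (i, j)
#'   order) and the `cull_cutoff` used.
#' @export
cull_pairs <- function(traj, cutoff = NULL) {
  stopifnot(inherits(traj, "FrameSeries"))
  n <- n_sites(traj)
  if (n < 2) {
    warning("fewer than 2 sites: empty pair set")
    return(structure(list(i = integer(), j = integer(),
                          cull_cutoff = cutoff), class = "PairSet"))
  }
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  if (is.null(cutoff) || !is.finite(cutoff)) {
    return(structure(list(i = ii, j = jj, cull_cutoff = NULL),
                     class = "PairSet"))
  }
  keep <- rep(FALSE, length(ii))
  c2 <- cutoff^2
  for (k in seq_len(n_frames(traj))) {
    todo <- which(!keep)
    if (length(todo) == 0) break
    xyz <- traj$coords[k, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    box <- traj$box[k, ]
    d2 <- 0
    for (ax in 1:3) {
      dd <- xyz[ii[todo], ax] - xyz[jj[todo], ax]
      dd <- dd - box[ax] * round(dd / box[ax])
      d2 <- d2 + dd * dd
    }
    keep[todo[d2 <= c2]] <- TRUE
  }
  structure(list(i = ii[keep], j = jj[keep], cull_cutoff = cutoff),
            class = "PairSet")
}

#' @export
print.PairSet <- function(x, ...) {
  cat("PairSet:", length(x$i), "pairs",
      if (!is.null(x$cull_cutoff)) sprintf("(culled at %g A)", x$cull_cutoff)
      else "(all pairs)", "\n")
  invisible(x)
}

#' Minimum-image distance time series for a set of site pairs
#'
#' Each frame uses that frame's own box (the cell deforms during poration).
#' No unwrapping across the boundary is attempted: the minimum image at each
#' frame is the definition of the distance.
#'
#' @param traj a [frame_series()].
#' @param pairs a `PairSet` from [cull_pairs()].
#' @return A `DistanceSeries`: list with `times`, the pair index vectors
#'   `i`, `j`, and `d`, a `frames x pairs` matrix of distances (Angstrom).
#' @export
pair_distance_series <- function(traj, pairs) {
  stopifnot(inherits(traj, "FrameSeries"), inherits(pairs, "PairSet"))
  n <- n_sites(traj)
  if (length(pairs$i) > 0 && (max(pairs$j) > n || min(pairs$i) < 1))
    stop("pair indices out of range")
  d2 <- matrix(0, n_frames(traj), length(pairs$i))
  for (ax in 1:3) {
    dd <- traj$coords[, pairs$i, ax, drop = FALSE] -
          traj$coords[, pairs$j, ax, drop = FALSE]
    dim(dd) <- dim(dd)[1:2]
    dd <- dd - traj$box[, ax] * round(dd / traj$box[, ax])
    d2 <- d2 + dd * dd
  }
  structure(list(times = traj$times, i = pairs$i, j = pairs$j, d = sqrt(d2)),
            class = "DistanceSeries")
}

#' Non-negative rate of change of pairwise distances
#'
#' First-order forward differences of each distance trace, taken in absolute
#' value and assigned to the midpoint time grid `t_k + dt/2`, so that the
#' fast rate series aligns naturally with an interpolated slow activity.
#'
#' @param series a `DistanceSeries` from [pair_distance_series()].
#' @param dt frame spacing in ps; defaults to the spacing of `series$times`.
#' @return A `RateSeries`: list with midpoint `times`, pair vectors `i`, `j`,
#'   and `r`, a `(frames-1) x pairs` matrix of |dX/dt| in Angstrom/ps.
#' @export
rate_series <- function(series, dt = NULL) {
  stopifnot(inherits(series, "DistanceSeries"))
  nf <- nrow(series$d)
  if (nf < 2) stop("degenerate input: rate series needs at least 2 frames")
  if (is.null(dt)) dt <- series$times[2] - series$times[1]
  if (dt <= 0) stop("dt must be positive")
  r <- abs(series$d[-1L, , drop = FALSE] - series$d[-nf, , drop = FALSE]) / dt
  structure(list(times = series$times[-nf] + dt / 2,
                 i = series$i, j = series$j, r = r),
            class = "RateSeries")
}
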