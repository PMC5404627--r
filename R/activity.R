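#' Parameters of the two-cutoff hysteresis contact graph
#'
#' Two distance thresholds bracket a buffer zone for recrossing suppression:
#' an edge forms when a pair distance drops below `low_cutoff` and breaks
#' only when it rises above `high_cutoff`, so fluctuations inside
#' `[low, high]` never generate events. Defaults follow the customary values
#' for a lipid phosphorus contact graph: 11 and 13 Angstrom (the lower value
#' matters most; the upper value is typically set 1-2 Angstrom higher).
#' `smoothing_sigma` is the Gaussian temporal smoothing of the event rate; as
#' a rule of thumb use about 5% of the trajectory window length.
#'
#' @param low_cutoff,high_cutoff distance thresholds, Angstrom.
#' @param smoothing_sigma temporal smoothing, ps.
#' @return A `GraphParams` object.
#' @export
graph_params <- function(low_cutoff = 11, high_cutoff = 13,
                         smoothing_sigma = 1) {
  if (!(low_cutoff > 0 && high_cutoff > low_cutoff))
    stop("need 0 < low_cutoff < high_cutoff")
  if (smoothing_sigma <= 0) stop("smoothing_sigma must be positive")
  structure(list(low_cutoff = low_cutoff, high_cutoff = high_cutoff,
                 smoothing_sigma = smoothing_sigma), class = "GraphParams")
}

#' Detect contact forming/breaking events with hysteresis
#'
#' Runs a two-state machine independently along each pair's distance trace.
#' The initial state at the first frame is PRESENT iff `d < low_cutoff`
#' (a start inside the buffer zone counts as ABSENT, which avoids phantom
#' breaking events from borderline starting contacts). ABSENT -> PRESENT when
#' `d < low_cutoff` emits a forming event at that frame's time;
#' PRESENT -> ABSENT when `d > high_cutoff` emits a breaking event; distances
#' inside `[low, high]` never change state.
#'
#' @param series a `DistanceSeries` from [pair_distance_series()].
#' @param params a [graph_params()].
#' @return An `EventList`: data.frame with columns `i`, `j`, `frame`
#'   (0-based), `time` (ps) and `kind` (`"forming"`/`"breaking"`).
#' @export
detect_edge_events <- function(series, params) {
  stopifnot(inherits(series, "DistanceSeries"), inherits(params, "GraphParams"))
  lo <- params$low_cutoff; hi <- params$high_cutoff
  out <- vector("list", length(series$i))
  for (p in seq_along(series$i)) {
    d <- series$d[, p]
    sig <- rep(NA_integer_, length(d))
    sig[d < lo] <- 1L
    sig[d > hi] <- 0L
    sig[1] <- if (d[1] < lo) 1L else 0L
    state <- sig[cummax(seq_along(sig) * !is.na(sig))]  # last-observation fill
    chg <- which(diff(state) != 0L) + 1L
    if (length(chg) == 0) next
    out[[p]] <- data.frame(i = series$i[p], j = series$j[p],
                           frame = chg - 1L, time = series$times[chg],
                           kind = ifelse(state[chg] == 1L,
                                         "forming", "breaking"),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  ev <- if (length(out) == 0) {
    data.frame(i = integer(), j = integer(), frame = integer(),
               time = numeric(), kind = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  ev <- ev[order(ev$time, ev$i, ev$j), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("EventList", "data.frame")
  ev
}

# truncated unit-mass Gaussian kernel mass (+-4 sigma)
.g4_mass <- 1 - 2 * stats::pnorm(-4)

#' Smoothed event-rate activity
#'
#' The activity a(t) is a Gaussian kernel rate estimate of the event times of
#' one kind: a sum of unit-mass Gaussians (sd `sigma`, truncated at +-4 sigma
#' and renormalized) centred on each event, evaluated on the frame grid.
#' Units are events/ps, so the time integral of a(t) recovers the event
#' count. An empty event list yields the all-zero trace — the zero-valued
#' activity case the dependence estimators must tolerate.
#'
#' @param events an `EventList` from [detect_edge_events()].
#' @param kind `"forming"` or `"breaking"`.
#' @param sigma Gaussian smoothing, ps.
#' @param grid time grid (ps) on which to evaluate the activity.
#' @return An `ActivityTrace`: list with `times`, `a` (>= 0, events/ps),
#'   `kind` and `params` provenance.
#' @export
smooth_event_activity <- function(events, kind = c("breaking", "forming"),
                                  sigma, grid) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be positive")
  te <- events$time[events$kind == kind]
  a <- rep(0, length(grid))
  if (length(te) > 0) {
    for (t0 in te) {
      w <- abs(grid - t0) <= 4 * sigma
      a[w] <- a[w] + stats::dnorm(grid[w], mean = t0, sd = sigma) / .g4_mass
    }
  }
  activity_trace(grid, a, kind = kind,
                 params = list(sigma = sigma, n_events = length(te)))
}

# internal constructor enforcing the non-negativity invariant
activity_trace <- function(times, a, kind, params = list()) {
  if (length(times) != length(a)) stop("times/a length mismatch")
  if (any(!is.finite(a)) || any(a < 0))
    stop("activity trace must be finite and non-negative everywhere")
  structure(list(times = as.numeric(times), a = as.numeric(a), kind = kind,
                 params = params), class = "ActivityTrace")
}

#' @export
print.ActivityTrace <- function(x, ...) {
  cat(sprintf("ActivityTrace [%s]: %d points, t = %g..%g ps, max a = %g\n",
              x$kind, length(x$a), min(x$times), max(x$times), max(x$a)))
  invisible(x)
}

#' Unit-cell dimension as a geometric activity
#'
#' During anisotropic processes such as electropore formation under NPT, the
#' periodic cell deforms (z compresses, x/y elongate), so a raw box edge
#' length is itself a usable slow activity marker. The trace is the per-frame
#' edge length in Angstrom, unsmoothed, strictly positive by construction.
#'
#' @param traj a [frame_series()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return An `ActivityTrace` of kind `box_x`/`box_y`/`box_z`.
#' @export
box_dimension_activity <- function(traj, axis = c("z", "x", "y")) {
  stopifnot(inherits(traj, "FrameSeries"))
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  activity_trace(traj$times, traj$box[, ax], kind = paste0("box_", axis))
}

#' Write / read an activity trace as TSV
#'
#' Two columns (time ps, activity) after `#`-prefixed provenance header lines
#' naming the kind and parameters. Values round-trip at full double
#' precision.
#'
#' @param trace an `ActivityTrace`.
#' @param path file path.
#' @return `path` invisibly; `read_activity_tsv` returns the `ActivityTrace`.
#' @export
write_activity_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "ActivityTrace"))
  hdr <- c(paste0("# kind=", trace$kind),
           vapply(names(trace$params), function(nm)
             paste0("# ", nm, "=", format(trace$params[[nm]], digits = 17)),
             character(1)),
           "# time_ps\tactivity")
  body <- sprintf("%.17g\t%.17g", trace$times, trace$a)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_activity_tsv
#' @export
read_activity_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  kind <- sub("^# kind=", "", hdr[startsWith(hdr, "# kind=")])
  if (length(kind) != 1) stop("activity file lacks a '# kind=' header: ", path)
  params <- list()
  for (h in hdr[grepl("^# [A-Za-z_]+=", hdr) & !startsWith(hdr, "# kind=")]) {
    kv <- sub("^# ", "", h)
    key <- sub("=.*$", "", kv)
    params[[key]] <- suppressWarnings(as.numeric(sub("^[^=]*=", "", kv)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  tm <- as.numeric(vapply(parts, `[[`, "", 1L))
  a <- as.numeric(vapply(parts, `[[`, "", 2L))
  activity_trace(tm, a, kind = kind, params = params)
}
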