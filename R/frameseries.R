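#' Construct a FrameSeries
#'
#' A FrameSeries holds a trajectory of representative sites: a uniform time
#' grid (ps), per-frame coordinates (Angstrom) and per-frame orthorhombic box
#' edge lengths (Angstrom), plus per-site metadata identifying the residue
#' each site represents.
#'
#' @param times numeric vector of frame times in ps, strictly increasing with
#'   uniform spacing.
#' @param coords numeric array of dimension `frames x sites x 3`, Angstrom.
#' @param box numeric matrix of dimension `frames x 3`, orthorhombic box edge
#'   lengths in Angstrom, strictly positive.
#' @param site_meta data.frame with one row per site and columns `resid`
#'   (integer), `resname`, `atom`, `chain` (character). Residue identity is
#'   the tuple (resname, resid, chain) so large solvent sets survive residue
#'   number wrap-around.
#' @return An object of class `FrameSeries`.
#' @export
frame_series <- function(times, coords, box, site_meta) {
  times <- as.numeric(times)
  if (is.matrix(box)) box <- unname(as.matrix(box)) else box <- matrix(as.numeric(box), ncol = 3)
  storage.mode(box) <- "double"
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x sites x 3 array")
  storage.mode(coords) <- "double"
  fs <- structure(list(times = times, coords = coords, box = box,
                       site_meta = as.data.frame(site_meta)),
                  class = "FrameSeries")
  validate_frame_series(fs)
  fs
}

validate_frame_series <- function(fs) {
  nf <- dim(fs$coords)[1]
  if (length(fs$times) != nf)
    stop("times length (", length(fs$times), ") != frame count (", nf, ")")
  if (nrow(fs$box) != nf)
    stop("box rows != frame count")
  if (nrow(fs$site_meta) != dim(fs$coords)[2])
    stop("site_meta rows != site count")
  if (!all(is.finite(fs$coords)))
    stop("non-finite coordinates in FrameSeries")
  if (!all(is.finite(fs$box)) || any(fs$box <= 0))
    stop("box components must be finite and strictly positive in every frame")
  if (nf > 1) {
    dts <- diff(fs$times)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (max(abs(dts - dts[1])) >= 1e-6 * dts[1])
      stop("times must be uniformly spaced (max |dt_k - dt_0| < 1e-6 dt_0)")
  }
  invisible(fs)
}

#' @export
print.FrameSeries <- function(x, ...) {
  nf <- n_frames(x); ns <- n_sites(x)
  cat("FrameSeries:", nf, "frames x", ns, "sites\n")
  if (nf > 0) {
    cat(sprintf("  time %g .. %g ps (dt = %g ps)\n", x$times[1], x$times[nf],
                if (nf > 1) x$times[2] - x$times[1] else NA))
    cat(sprintf("  box[1] = %.2f x %.2f x %.2f A\n",
                x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  }
  if (ns > 0)
    cat("  residues:", paste(utils::head(unique(x$site_meta$resname), 5),
                             collapse = " "),
        if (length(unique(x$site_meta$resname)) > 5) "..." else "", "\n")
  invisible(x)
}

#' @rdname frame_series
#' @param fs a `FrameSeries`.
#' @export
n_frames <- function(fs) dim(fs$coords)[1]

#' @rdname frame_series
#' @export
n_sites <- function(fs) dim(fs$coords)[2]

# frame spacing in ps (NA for single-frame series)
frame_dt <- function(fs) {
  if (n_frames(fs) < 2) return(NA_real_)
  fs$times[2] - fs$times[1]
}

# residue identity keys, one per site
residue_key <- function(meta) {
  paste(meta$resname, meta$resid, meta$chain, sep = "\r")
}
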