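#' Read a multi-model PDB or GRO trajectory
#'
#' Reads per-frame coordinates of all atoms plus the orthorhombic unit-cell
#' edge lengths. PDB coordinates are taken as Angstrom; GRO values are nm and
#' converted to Angstrom on read. Only orthorhombic cells are supported:
#' a PDB `CRYST1` record with angles other than 90 degrees, or a GRO box line
#' with non-zero off-diagonal components, is a hard error rather than a
#' silent approximation.
#'
#' Neither format carries a reliable time stamp per frame (GRO titles with a
#' `t=` field are honoured when present on every frame and uniformly spaced),
#' so the frame spacing `dt` must be supplied; frames are placed on the grid
#' `time0 + (0:(frames-1)) * dt`.
#'
#' @param path path to the trajectory file.
#' @param format `"pdb"`, `"gro"` or `"auto"` (by file extension).
#' @param dt frame spacing in ps used when the file has no time stamps.
#' @param time0 time of the first frame, ps.
#' @return A [frame_series()] with all atoms as sites, in file order.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "gro"),
                            dt = 1, time0 = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot infer trajectory format from extension '",
                          ext, "'; pass format explicitly"))
  }
  if (dt <= 0) stop("dt must be positive")
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") read_pdb_frames(lines, dt, time0, path)
  else read_gro_frames(lines, dt, time0, path)
}

# ---- PDB ------------------------------------------------------------------

parse_cryst1 <- function(line, path) {
  abc <- suppressWarnings(as.numeric(c(substr(line, 7, 15),
                                       substr(line, 16, 24),
                                       substr(line, 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(line, 34, 40),
                                       substr(line, 41, 47),
                                       substr(line, 48, 54))))
  ang[is.na(ang)] <- 90
  if (any(is.na(abc)) || any(abc <= 0))
    stop("malformed CRYST1 record in ", path)
  if (any(abs(ang - 90) > 1e-3))
    stop("unsupported geometry: triclinic cell (CRYST1 angles ",
         paste(ang, collapse = " "), ") in ", path,
         "; only orthorhombic cells are supported")
  abc
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  at <- lines[rec == "ATOM  " | rec == "HETATM"]
  if (length(at) == 0) stop("format error: no ATOM/HETATM records in frame")
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  if (any(is.na(xyz))) stop("format error: unreadable PDB coordinates")
  meta <- data.frame(resid = as.integer(substr(at, 23, 26)),
                     resname = trimws(substr(at, 18, 21)),
                     atom = trimws(substr(at, 13, 16)),
                     chain = substr(at, 22, 22),
                     stringsAsFactors = FALSE)
  list(xyz = xyz, meta = meta)
}

read_pdb_frames <- function(lines, dt, time0, path) {
  rec <- substr(lines, 1, 6)
  cryst_idx <- which(rec == "CRYST1")
  model_idx <- which(rec == "MODEL ")
  end_idx <- which(rec == "ENDMDL")
  if (length(cryst_idx) == 0)
    stop("format error: PDB trajectory has no CRYST1 box record (", path, ")")
  if (length(model_idx) == 0) {
    blocks <- list(seq_along(lines))
  } else {
    if (length(end_idx) != length(model_idx))
      stop("format error: unbalanced MODEL/ENDMDL in ", path)
    blocks <- Map(seq, model_idx, end_idx)
  }
  # CRYST1 per file applies to all models unless repeated inside them
  global_box <- parse_cryst1(lines[cryst_idx[1]], path)
  frames <- lapply(blocks, function(ix) {
    sub <- lines[ix]
    ci <- which(substr(sub, 1, 6) == "CRYST1")
    box <- if (length(ci) > 0) parse_cryst1(sub[ci[1]], path) else global_box
    c(parse_pdb_atoms(sub), list(box = box))
  })
  assemble_frames(frames, dt, time0, path)
}

# ---- GRO ------------------------------------------------------------------

read_gro_frames <- function(lines, dt, time0, path) {
  frames <- list()
  times <- numeric()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1 || i + 1L + nat + 1L > length(lines) + 0L)
      stop("format error: malformed GRO frame header at line ", i, " of ", path)
    at <- lines[(i + 2L):(i + 1L + nat)]
    boxline <- lines[i + 2L + nat]
    vals <- suppressWarnings(as.numeric(strsplit(trimws(boxline), "\\s+")[[1]]))
    if (length(vals) != 3 && length(vals) != 9 || any(is.na(vals)))
      stop("format error: missing or malformed GRO box line in ", path)
    if (length(vals) == 9 && any(abs(vals[4:9]) > 1e-9))
      stop("unsupported geometry: triclinic GRO box in ", path)
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44))) * 10  # nm -> Angstrom
    if (any(is.na(xyz))) stop("format error: unreadable GRO coordinates")
    meta <- data.frame(resid = as.integer(substr(at, 1, 5)),
                       resname = trimws(substr(at, 6, 10)),
                       atom = trimws(substr(at, 11, 15)),
                       chain = "",
                       stringsAsFactors = FALSE)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm) == 1)
      as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    frames[[length(frames) + 1L]] <-
      list(xyz = xyz, meta = meta, box = vals[1:3] * 10)
    i <- i + 3L + nat
  }
  if (length(frames) == 0) stop("format error: no frames in ", path)
  fs <- assemble_frames(frames, dt, time0, path)
  # honour embedded "t=" stamps when complete and uniform
  if (!anyNA(times) && length(times) > 1) {
    dts <- diff(times)
    if (all(dts > 0) && max(abs(dts - dts[1])) < 1e-6 * dts[1])
      fs$times <- times
  }
  fs
}

assemble_frames <- function(frames, dt, time0, path) {
  nat <- vapply(frames, function(f) nrow(f$xyz), integer(1))
  if (length(unique(nat)) != 1)
    stop("format error: inconsistent atom count across frames in ", path,
         " (", paste(unique(nat), collapse = ", "), ")")
  key0 <- residue_key(frames[[1]]$meta)
  nf <- length(frames); ns <- nat[1]
  coords <- array(NA_real_, c(nf, ns, 3))
  box <- matrix(NA_real_, nf, 3)
  for (k in seq_len(nf)) {
    if (!identical(residue_key(frames[[k]]$meta), key0) ||
        !identical(frames[[k]]$meta$atom, frames[[1]]$meta$atom))
      stop("format error: site order differs between frames in ", path)
    coords[k, , ] <- frames[[k]]$xyz
    box[k, ] <- frames[[k]]$box
  }
  frame_series(times = time0 + (seq_len(nf) - 1) * dt, coords = coords,
               box = box, site_meta = frames[[1]]$meta)
}

# ---- selection ------------------------------------------------------------

#' Selection rules mapping residues to one representative atom
#'
#' Each rule pairs a residue name with the atom that stands in for the whole
#' molecule in the coarse-grained distance geometry (e.g. `POPC -> P`,
#' `SOL -> OW`). Matching is by exact residue name; a residue name may appear
#' in at most one rule.
#'
#' @param ... named arguments, `RESNAME = "ATOM"`, or a single named
#'   character vector.
#' @return A `SelectionSpec`.
#' @export
selection_spec <- function(...) {
  args <- c(...)
  if (length(args) == 0) {
    rules <- data.frame(resname = character(), atom = character(),
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("selection rules must be named: selection_spec(POPC = \"P\")")
    rules <- data.frame(resname = names(args), atom = unname(args),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(rules$resname))
    stop("each residue name may be matched by at most one rule")
  structure(list(rules = rules), class = "SelectionSpec")
}

#' Reduce a trajectory to one representative site per residue
#'
#' Applies a [selection_spec()]: every residue whose name matches a rule
#' contributes exactly the named atom; unmatched residues are dropped.
#' Output sites are ordered by residue id (then chain, then residue name);
#' times and box are unchanged.
#'
#' @param traj a [frame_series()].
#' @param spec a [selection_spec()].
#' @return A `FrameSeries` with one site per matched residue.
#' @export
select_representatives <- function(traj, spec) {
  stopifnot(inherits(traj, "FrameSeries"), inherits(spec, "SelectionSpec"))
  meta <- traj$site_meta
  want <- stats::setNames(spec$rules$atom, spec$rules$resname)
  matched <- meta$resname %in% names(want)
  hit <- matched & meta$atom == unname(want[meta$resname])
  # residues matched by a rule but lacking the named atom
  mk <- residue_key(meta)
  matched_res <- unique(mk[matched])
  hit_res <- unique(mk[hit])
  missing <- setdiff(matched_res, hit_res)
  if (length(missing) > 0)
    stop("selection error: residue(s) lacking the representative atom: ",
         paste(gsub("\r", "/", utils::head(missing, 10)), collapse = ", "),
         if (length(missing) > 10) " ..." else "")
  dup <- mk[hit][duplicated(mk[hit])]
  if (length(dup) > 0)
    stop("selection error: representative atom not unique in residue(s): ",
         paste(gsub("\r", "/", unique(utils::head(dup, 10))), collapse = ", "))
  idx <- which(hit)
  idx <- idx[order(meta$resid[idx], meta$chain[idx], meta$resname[idx])]
  frame_series(times = traj$times,
               coords = traj$coords[, idx, , drop = FALSE],
               box = traj$box,
               site_meta = meta[idx, , drop = FALSE])
}

#' Trim a trajectory to a frame window with a stride
#'
#' Frame indices are 0-based and inclusive by default, so
#' `trim_frames(x, 0, 9, 3)` keeps frames {0, 3, 6, 9}. GROMACS-style 1-based
#' frame numbers (as printed in the literature, e.g. a window "frames
#' 2001-2256") can be passed with `one_based = TRUE`. Times are preserved
#' from the input, not re-zeroed.
#'
#' @param traj a [frame_series()].
#' @param first,last first and last frame index (inclusive).
#' @param stride positive integer stride.
#' @param one_based interpret `first`/`last` as 1-based frame numbers.
#' @return The trimmed `FrameSeries`.
#' @export
trim_frames <- function(traj, first, last, stride = 1L, one_based = FALSE) {
  stopifnot(inherits(traj, "FrameSeries"))
  if (one_based) { first <- first - 1L; last <- last - 1L }
  nf <- n_frames(traj)
  if (stride < 1 || stride != round(stride)) stop("stride must be a positive integer")
  if (first < 0 || last < first || last >= nf)
    stop("bounds error: frame window [", first, ", ", last,
         "] invalid for ", nf, " frames (0-based inclusive)")
  keep <- seq.int(first, last, by = stride) + 1L
  frame_series(times = traj$times[keep],
               coords = traj$coords[keep, , , drop = FALSE],
               box = traj$box[keep, , drop = FALSE],
               site_meta = traj$site_meta)
}

# ---- heat-annotated structure output --------------------------------------

#' Write one frame as a PDB with heat values in the B-factor column
#'
#' Heat values are linearly rescaled per map to [0, 99.99] (the printable
#' B-factor range): the maximum heat maps to 99.99 and an all-zero map writes
#' all zeros. One file is written per requested frame, so a heat map can be
#' viewed on the moving canvas of a liquid trajectory frame by frame.
#'
#' @param traj a [frame_series()].
#' @param frame 0-based frame index to write.
#' @param heat a [heat_map()] (or bare numeric vector) with one value per site.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_heat_structure <- function(traj, frame, heat, path) {
  stopifnot(inherits(traj, "FrameSeries"))
  vals <- if (inherits(heat, "HeatMap")) heat$values else as.numeric(heat)
  if (length(vals) != n_sites(traj))
    stop("dimension error: heat has ", length(vals), " values for ",
         n_sites(traj), " sites")
  if (frame < 0 || frame >= n_frames(traj))
    stop("bounds error: frame ", frame, " not in [0, ", n_frames(traj) - 1, "]")
  k <- frame + 1L
  b <- if (max(vals) > 0) vals / max(vals) * 99.99 else rep(0, length(vals))
  meta <- traj$site_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[k, 1], traj$box[k, 2], traj$box[k, 3],
                     90, 90, 90), con)
  writeLines("MODEL        1", con)
  an <- ifelse(nchar(meta$atom) < 4, sprintf(" %-3s", meta$atom),
               sprintf("%-4s", meta$atom))
  writeLines(sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(nrow(meta)) %% 100000L, an, meta$resname,
                     ifelse(nzchar(meta$chain), meta$chain, "A"),
                     meta$resid %% 10000L,
                     traj$coords[k, , 1], traj$coords[k, , 2],
                     traj$coords[k, , 3], 1, b), con)
  writeLines(c("ENDMDL", "END"), con)
  invisible(path)
}
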