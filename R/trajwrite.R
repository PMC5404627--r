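#' Write a FrameSeries as a multi-model PDB or GRO trajectory
#'
#' `write_trajectory_pdb` writes one MODEL/ENDMDL block per frame with a
#' CRYST1 record inside each block (so per-frame boxes survive a round trip);
#' `write_trajectory_gro` writes consecutive GRO frames with `t=` time stamps
#' in the title and the box line in nm.
#'
#' @param traj a [frame_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "FrameSeries"))
  meta <- traj$site_meta
  an <- ifelse(nchar(meta$atom) < 4, sprintf(" %-3s", meta$atom),
               sprintf("%-4s", meta$atom))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(c(sprintf("MODEL     %4d", k),
                 sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                         traj$box[k, 1], traj$box[k, 2], traj$box[k, 3],
                         90, 90, 90),
                 sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         seq_len(nrow(meta)) %% 100000L, an, meta$resname,
                         ifelse(nzchar(meta$chain), meta$chain, "A"),
                         meta$resid %% 10000L,
                         traj$coords[k, , 1], traj$coords[k, , 2],
                         traj$coords[k, , 3], 1, 0),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_trajectory_pdb
#' @export
write_trajectory_gro <- function(traj, path) {
  stopifnot(inherits(traj, "FrameSeries"))
  meta <- traj$site_meta
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(c(sprintf("poremap frame t= %.6f", traj$times[k]),
                 sprintf("%5d", n_sites(traj)),
                 sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         meta$resid %% 100000L, meta$resname, meta$atom,
                         seq_len(nrow(meta)) %% 100000L,
                         traj$coords[k, , 1] / 10, traj$coords[k, , 2] / 10,
                         traj$coords[k, , 3] / 10),
                 sprintf("%10.5f%10.5f%10.5f", traj$box[k, 1] / 10,
                         traj$box[k, 2] / 10, traj$box[k, 3] / 10)), con)
  }
  invisible(path)
}
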