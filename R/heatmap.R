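#' Compress the dependence matrix to per-residue heat values
#'
#' The pairwise matrix R(i, j) is banded (only culled, spatially proximal
#' pairs are computed), so its columns compress to their average: the heat of
#' residue i is the mean of R(i, j) over the computed partners j of i.
#' Averaging over computed partners only — not all n-1 columns — avoids
#' systematically deflating residues in sparse neighbourhoods when solvent
#' culling is active. Residues with no computed partner get heat 0.
#'
#' @param R a `DependenceMatrix` from [dependence_matrix()].
#' @param resid optional residue ids aligned with site order (default
#'   `1:n`).
#' @param activity_kind optional provenance string.
#' @return A `HeatMap`: list with `values` (>= 0, one per site), `resid`,
#'   and provenance (`method`, `activity_kind`).
#' @export
compress_heatmap <- function(R, resid = NULL, activity_kind = NA_character_) {
  stopifnot(inherits(R, "DependenceMatrix"))
  cnt <- rowSums(R$mask)
  vals <- ifelse(cnt > 0, rowSums(R$R * R$mask) / pmax(cnt, 1), 0)
  if (is.null(resid)) resid <- seq_len(R$n)
  if (length(resid) != R$n) stop("resid length != site count")
  heat_map(vals, resid, method = R$method, activity_kind = activity_kind)
}

#' @rdname compress_heatmap
#' @param values non-negative numeric vector, one heat value per residue.
#' @param method provenance: dependence method used.
#' @export
heat_map <- function(values, resid = seq_along(values),
                     method = NA_character_, activity_kind = NA_character_) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("heat values must be finite and non-negative")
  if (length(resid) != length(values)) stop("resid/values length mismatch")
  structure(list(values = values, resid = resid, method = method,
                 activity_kind = activity_kind), class = "HeatMap")
}

#' @export
print.HeatMap <- function(x, ...) {
  cat(sprintf("HeatMap: %d residues, method=%s, activity=%s, max=%g\n",
              length(x$values), x$method, x$activity_kind,
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Rank residues by heat
#'
#' Residue ids sorted by descending heat value; ties break by ascending
#' residue id so the ranking is deterministic. Rankings are scale-invariant:
#' multiplying all heat (or dependence) values by a positive constant leaves
#' the order unchanged.
#'
#' @param heat a [heat_map()].
#' @param top_k how many residues to return (`<=` residue count).
#' @return Vector of `top_k` residue ids, hottest first.
#' @export
rank_residues <- function(heat, top_k = length(heat$values)) {
  stopifnot(inherits(heat, "HeatMap"))
  if (top_k < 1 || top_k > length(heat$values))
    stop("bounds error: top_k must be in [1, ", length(heat$values), "]")
  ord <- order(-heat$values, heat$resid)
  heat$resid[ord][seq_len(top_k)]
}

#' Export / import a heat map as TSV
#'
#' Two columns (residue id, heat value) after `#`-prefixed provenance header
#' lines (activity kind, method, and any parameters passed in `provenance`).
#' Values are written with full double precision so a write/read round trip
#' is bit exact.
#'
#' @param heat a [heat_map()].
#' @param path file path.
#' @param provenance named list of extra provenance fields (e.g. cutoffs,
#'   window, stride) recorded in the header.
#' @return `path` invisibly; `read_heatmap` returns the `HeatMap`.
#' @export
export_heatmap <- function(heat, path, provenance = list()) {
  stopifnot(inherits(heat, "HeatMap"))
  prov <- c(list(method = heat$method, activity_kind = heat$activity_kind),
            provenance)
  hdr <- c(vapply(names(prov), function(nm)
    paste0("# ", nm, "=", format(prov[[nm]], digits = 17)), character(1)),
    "# resid\theat")
  writeLines(c(hdr, sprintf("%d\t%.17g", as.integer(heat$resid),
                            heat$values)), path)
  invisible(path)
}

#' @rdname export_heatmap
#' @export
read_heatmap <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get1 <- function(key) {
    h <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(h) == 1) sub("^[^=]*=", "", h) else NA_character_
  }
  if (length(body) == 0)
    return(heat_map(numeric(), integer(), method = get1("method"),
                    activity_kind = get1("activity_kind")))
  parts <- strsplit(body, "\t", fixed = TRUE)
  heat_map(as.numeric(vapply(parts, `[[`, "", 2L)),
           as.integer(vapply(parts, `[[`, "", 1L)),
           method = get1("method"), activity_kind = get1("activity_kind"))
}
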