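#' Interpolate an activity trace onto the rate midpoint grid
#'
#' The fast rate series lives on midpoint times `t_k + dt/2`; the slow
#' activity is linearly interpolated onto that grid (the rate grid is the
#' information-limiting one, so the activity moves, not the rates).
#'
#' @param activity an `ActivityTrace`.
#' @param rate_times numeric vector of target times (ps); must lie within the
#'   activity's time span.
#' @return Numeric vector of interpolated activity values.
#' @export
align_activity <- function(activity, rate_times) {
  stopifnot(inherits(activity, "ActivityTrace"))
  tol <- 1e-9 * max(1, diff(range(activity$times)))
  if (min(rate_times) < min(activity$times) - tol ||
      max(rate_times) > max(activity$times) + tol)
    stop("extrapolation error: rate grid [", min(rate_times), ", ",
         max(rate_times), "] outside activity span [", min(activity$times),
         ", ", max(activity$times), "]")
  stats::approx(activity$times, activity$a, xout = rate_times, rule = 2)$y
}

#' Pearson dependence with noise-floor zeroing
#'
#' Sample Pearson correlation of a rate series with the aligned activity.
#' Negative correlations measure the noise floor and are set to zero; if
#' either input has zero variance the dependence is defined as 0 (a frozen
#' pair carries no information about the activity).
#'
#' @param r,a equal-length numeric vectors (length >= 3).
#' @return A coefficient in `[0, 1]`.
#' @export
pearson_dependence <- function(r, a) {
  if (length(r) != length(a))
    stop("dimension error: length(r) != length(a)")
  if (length(r) < 3) stop("need at least 3 samples")
  if (stats::sd(r) == 0 || stats::sd(a) == 0) return(0)
  max(0, stats::cor(r, a))
}

# robust scale for standardization: IQR-based, sd fallback
robust_scale <- function(x) {
  s <- stats::IQR(x) / 1.349
  if (s <= 0) s <- stats::sd(x)
  s
}

#' Mutual information via adaptive-bandwidth kernel density estimation
#'
#' Plug-in estimate `I = (1/N) sum_k log[ f(r_k, a_k) / (f(r_k) f(a_k)) ]`
#' (nats), with all three densities leave-one-out Gaussian kernel estimates
#' whose per-sample bandwidths follow the Abramson square-root law: each
#' variable is standardized to unit interquartile-range-based scale, a pilot
#' density with fixed Silverman bandwidth is evaluated at the samples, and
#' the kernel centred on sample k gets bandwidth
#' `h * (f_pilot(x_k) / G)^(-1/2)` with `G` the geometric mean of the pilot
#' densities. Dense regions — including an exact point mass at zero, the
#' signature of an activity that is zero-valued for part of the window — thus
#' get narrow kernels, and sparse tails wide ones. The final global
#' bandwidth is `bw_adjust` times the Silverman value: plug-in functional
#' estimates tolerate more variance than density-optimal smoothing, and
#' undersmoothing keeps the joint-density bias on strongly dependent data
#' small (see the methods vignette for the bias arithmetic).
#'
#' The estimator is deterministic and exactly symmetric in its arguments.
#' Negative estimates are noise and clamped to 0, mirroring the Pearson
#' noise-floor treatment. Below `min_n` samples the KDE is unreliable: the
#' function warns and returns 0.
#'
#' @param r,a equal-length finite numeric vectors.
#' @param bw_adjust multiplier on the Silverman bandwidth (default 0.5).
#' @param min_n minimum sample count (default 50).
#' @return Mutual information in nats, `>= 0`.
#' @export
mutual_information <- function(r, a, bw_adjust = 0.5, min_n = 50) {
  if (length(r) != length(a))
    stop("dimension error: length(r) != length(a)")
  if (any(!is.finite(r)) || any(!is.finite(a)))
    stop("domain error: non-finite values in mutual_information inputs")
  n <- length(r)
  if (n < min_n) {
    warning("mutual_information: fewer than ", min_n,
            " samples; KDE unreliable, returning 0")
    return(0)
  }
  if (stats::sd(r) == 0 || stats::sd(a) == 0) return(0)
  prep <- function(x) {
    x <- (x - stats::median(x)) / robust_scale(x)
    # Silverman's rule on the standardized sample
    h0 <- 0.9 * min(stats::sd(x), stats::IQR(x) / 1.349) * n^(-1 / 5)
    if (h0 <= 0) h0 <- 0.9 * stats::sd(x) * n^(-1 / 5)
    fp <- kde_pilot_1d(x, h0)
    lam <- exp(0.5 * (mean(log(fp)) - log(fp)))  # (f/G)^(-1/2)
    lam <- pmin(pmax(lam, 0.05), 20)             # numerical guard rails
    list(x = x, h = bw_adjust * h0, lam = lam)
  }
  pr <- prep(r); pa <- prep(a)
  max(0, mi_adaptive_loo(pr$x, pa$x, pr$h, pa$h, pr$lam, pa$lam))
}

#' Dependence matrix between pairwise rates and the global activity
#'
#' For every culled site pair (i, j), quantifies the statistical dependence
#' of the pair's distance rate |dX_ij/dt| with the activity a(t) aligned onto
#' the rate grid, yielding the positive symmetric matrix R(i, j). Entries
#' outside the culled pair set and the diagonal are 0.
#'
#' @param rates a `RateSeries` from [rate_series()].
#' @param activity an `ActivityTrace` spanning the rate grid.
#' @param method `"pearson"` or `"mutual_information"`.
#' @param n number of sites (defaults to the largest pair index).
#' @param ... passed on to [mutual_information()].
#' @return A `DependenceMatrix`: list with `n`, the symmetric non-negative
#'   `R` (n x n), logical `mask` of computed pairs, and `method`.
#' @export
dependence_matrix <- function(rates, activity,
                              method = c("pearson", "mutual_information"),
                              n = NULL, ...) {
  stopifnot(inherits(rates, "RateSeries"))
  method <- match.arg(method)
  np <- length(rates$i)
  if (np == 0) stop("empty-matrix error: no pairs in rate series")
  if (is.null(n)) n <- max(rates$j)
  av <- align_activity(activity, rates$times)
  vals <- if (method == "pearson") {
    if (stats::sd(av) == 0) {
      rep(0, np)
    } else {
      sds <- apply(rates$r, 2, stats::sd)
      v <- rep(0, np)
      ok <- sds > 0
      if (any(ok)) v[ok] <- pmax(0, as.vector(stats::cor(rates$r[, ok, drop = FALSE], av)))
      v
    }
  } else {
    vapply(seq_len(np), function(p)
      mutual_information(rates$r[, p], av, ...), numeric(1))
  }
  R <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  idx <- cbind(rates$i, rates$j)
  R[idx] <- vals; R[idx[, 2:1, drop = FALSE]] <- vals
  mask[idx] <- TRUE; mask[idx[, 2:1, drop = FALSE]] <- TRUE
  structure(list(n = n, R = R, mask = mask, method = method),
            class = "DependenceMatrix")
}

#' @export
print.DependenceMatrix <- function(x, ...) {
  cat(sprintf("DependenceMatrix [%s]: %d sites, %d computed pairs, max R = %g\n",
              x$method, x$n, sum(x$mask) / 2, max(x$R)))
  invisible(x)
}

#' Write a dependence matrix to disk
#'
#' `write_dependence_matrix` writes the dense matrix as whitespace-delimited
#' text after a one-line `#` header (n, method); `write_dependence_triplets`
#' writes the sparse upper-triangle triplet TSV (i, j, value) preferred for
#' solvent-scale systems.
#'
#' @param dm a `DependenceMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dependence_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "DependenceMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d method=%s", dm$n, dm$method), con)
  utils::write.table(format(dm$R, digits = 17, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dependence_matrix
#' @export
write_dependence_triplets <- function(dm, path) {
  stopifnot(inherits(dm, "DependenceMatrix"))
  up <- which(upper.tri(dm$mask) & dm$mask, arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  writeLines(c(sprintf("# n=%d method=%s", dm$n, dm$method),
               "# i\tj\tvalue",
               sprintf("%d\t%d\t%.17g", up[, 1], up[, 2], dm$R[up])), path)
  invisible(path)
}
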