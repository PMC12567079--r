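#' Recurrence matrix of a scalar series
#'
#' The binary N x N matrix with `R[i, j] = 1` iff `|y_i - y_j| <= radius`.
#' The comparison is inclusive, so radius 0 reproduces exact-match
#' recurrence. The matrix is symmetric with a unit main diagonal by
#' construction. No phase-space embedding is applied: recurrence is read
#' directly on the scalar height series (an optional `(m, tau)` delay
#' embedding is available via `embed_dim`/`embed_lag` but off by default).
#'
#' @param y Numeric vector (or a [display_series()]).
#' @param radius Recurrence radius `r`, in the units of `y` (pixels for
#'   tracked series); must be >= 0.
#' @param embed_dim,embed_lag Optional delay-embedding dimension and lag;
#'   with `embed_dim > 1` recurrence uses the maximum norm across embedded
#'   coordinates.
#' @return An object of class `recurrence_matrix`: list with `R` (0/1
#'   integer matrix), `radius` and `n`.
#' @export
recurrence_matrix <- function(y, radius, embed_dim = 1L, embed_lag = 1L) {
  if (inherits(y, "display_series")) y <- y$y
  y <- as.numeric(y)
  if (!length(y)) stop("series is empty")
  if (length(y) < 2L) stop("series must have at least 2 samples")
  if (radius < 0) stop("`radius` must be >= 0")
  if (embed_dim < 1L) stop("`embed_dim` must be >= 1")
  n <- length(y) - (embed_dim - 1L) * embed_lag
  if (n < 2L) stop("series too short for the requested embedding")
  R <- matrix(TRUE, n, n)
  for (d in seq_len(embed_dim)) {
    yd <- y[seq_len(n) + (d - 1L) * embed_lag]
    R <- R & (abs(outer(yd, yd, "-")) <= radius)
  }
  structure(list(R = R + 0L, radius = radius, n = n),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d, radius %.4g, RR %.1f%%\n",
              x$n, x$n, x$radius, recurrence_rate(x)))
  invisible(x)
}

as_rmat <- function(R) {
  if (inherits(R, "recurrence_matrix")) R$R else as.matrix(R)
}

#' Recurrence rate
#'
#' Percentage of cells of the recurrence matrix that are recurrent, main
#' diagonal included. Reads as the inverse variability of flight heights:
#' the fewer distinct heights a display visits, the higher its RR.
#'
#' @param R A `recurrence_matrix` (or bare 0/1 matrix).
#' @return Percentage in `[100/N, 100]`.
#' @export
recurrence_rate <- function(R) {
  m <- as_rmat(R)
  100 * sum(m) / length(m)
}

#' Histogram of diagonal or vertical line lengths
#'
#' Counts maximal runs of recurrent points along diagonals parallel to
#' (and excluding) the main diagonal, or along verticals with the
#' main-diagonal cell removed before run construction (a Theiler window of
#' 1, so the trivially self-recurrent line of identity never contributes).
#' Both triangles are counted; for a symmetric matrix the vertical and
#' horizontal histograms coincide.
#'
#' @param R A `recurrence_matrix` (or bare 0/1 matrix).
#' @param orientation `"diagonal"` or `"vertical"`.
#' @param exclude_diag Drop the main diagonal (default). Setting `FALSE`
#'   includes the line of identity, for sensitivity analysis.
#' @return A named integer vector: `counts[l]` = number of maximal lines of
#'   length `l` (names are lengths; empty when no line exists).
#' @export
line_histogram <- function(R, orientation = c("diagonal", "vertical"),
                           exclude_diag = TRUE) {
  orientation <- match.arg(orientation)
  m <- as_rmat(R)
  n <- nrow(m)
  lengths_acc <- integer(0)
  if (orientation == "diagonal") {
    ks <- if (exclude_diag) c(-(n - 1):-1, 1:(n - 1)) else -(n - 1):(n - 1)
    for (k in ks) {
      idx <- if (k >= 0) cbind(seq_len(n - k), seq_len(n - k) + k)
      else cbind(seq_len(n + k) - k, seq_len(n + k))
      v <- m[idx]
      r <- rle(v)
      lengths_acc <- c(lengths_acc, r$lengths[r$values == 1L])
    }
  } else {
    for (j in seq_len(n)) {
      v <- m[, j]
      if (exclude_diag) v[j] <- 0L
      r <- rle(v)
      lengths_acc <- c(lengths_acc, r$lengths[r$values == 1L])
    }
  }
  if (!length(lengths_acc)) return(integer(0))
  tab <- table(lengths_acc)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

line_ratio <- function(hist, min_len) {
  if (!length(hist)) return(0)
  l <- as.integer(names(hist))
  denom <- sum(l * hist)
  if (denom == 0) return(0)
  100 * sum((l * hist)[l >= min_len]) / denom
}

#' Determinism
#'
#' Weighted percentage of off-diagonal recurrent points lying on diagonal
#' lines of length at least `l_min`: how predictable future motion is as a
#' function of past motion. Returns 0 when the matrix has no off-diagonal
#' recurrence.
#'
#' @param R A `recurrence_matrix` (or 0/1 matrix).
#' @param l_min Minimum diagonal line length (default 2).
#' @param exclude_diag Passed to [line_histogram()].
#' @return Percentage in `[0, 100]`.
#' @export
determinism <- function(R, l_min = 2L, exclude_diag = TRUE) {
  line_ratio(line_histogram(R, "diagonal", exclude_diag), l_min)
}

#' Laminarity
#'
#' Weighted percentage of off-diagonal recurrent points lying on vertical
#' lines of length at least `v_min`: the share of the series spent in
#' stationary episodes (males holding the perch).
#'
#' @param R A `recurrence_matrix` (or 0/1 matrix).
#' @param v_min Minimum vertical line length (default 2).
#' @param exclude_diag Passed to [line_histogram()].
#' @return Percentage in `[0, 100]`.
#' @export
laminarity <- function(R, v_min = 2L, exclude_diag = TRUE) {
  line_ratio(line_histogram(R, "vertical", exclude_diag), v_min)
}

#' Microstate (recurrence) entropy
#'
#' Shannon entropy, in nats, of the distribution of q x q binary
#' sub-blocks ("microstates") of the recurrence matrix. Blocks are sampled
#' uniformly with replacement from all `(N-q+1)^2` top-left positions
#' (blocks may straddle the main diagonal); with `exhaustive = TRUE` every
#' position is enumerated instead, giving the exact plug-in entropy of the
#' full microstate distribution. For the default `q = 2` the maximum is
#' `ln 16`, attained when all 16 microstates are equally probable. This is
#' the metric sensitive to subtle changes in display dynamics.
#'
#' @param R A `recurrence_matrix` (or 0/1 matrix).
#' @param q Microstate side length (default 2).
#' @param n_samples Number of sampled block positions (default 10000).
#' @param seed Optional RNG seed for the sampling, making the estimate
#'   reproducible without touching the global RNG stream.
#' @param exhaustive Enumerate all positions instead of sampling.
#' @return Entropy in nats, in `[0, q^2 * ln 2]`.
#' @export
microstate_entropy <- function(R, q = 2L, n_samples = 10000L, seed = NULL,
                               exhaustive = FALSE) {
  m <- as_rmat(R)
  n <- nrow(m)
  q <- as.integer(q)
  if (n < q) stop("matrix smaller than the microstate size")
  npos <- n - q + 1L
  pow2 <- 2^(seq_len(q * q) - 1L)

  block_ids <- function(is, js) {
    id <- rep(1, length(is))
    b <- 0L
    for (dj in 0:(q - 1L)) for (di in 0:(q - 1L)) {
      b <- b + 1L
      id <- id + m[cbind(is + di, js + dj)] * pow2[b]
    }
    id
  }

  if (exhaustive) {
    is <- rep(seq_len(npos), times = npos)
    js <- rep(seq_len(npos), each = npos)
    ids <- block_ids(is, js)
  } else {
    if (n_samples < 1L) stop("`n_samples` must be >= 1")
    draw <- function() {
      is <- sample.int(npos, n_samples, replace = TRUE)
      js <- sample.int(npos, n_samples, replace = TRUE)
      block_ids(is, js)
    }
    ids <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  p <- tabulate(ids, nbins = 2^(q * q))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) + 0   # `+ 0` normalises -0 to 0
}

#' Select the recurrence radius by entropy maximisation
#'
#' Evaluates the microstate entropy over a grid of candidate radii and
#' returns the smallest radius attaining the maximum (maximum-entropy
#' principle: the radius at which the recurrence matrix carries the most
#' information about the dynamics). Default candidates are 50 values
#' evenly spanning 1% to 100% of the series range; a constant series has
#' no scale, so its single candidate is 0.
#'
#' @param y Numeric vector or [display_series()].
#' @param candidates Candidate radii; `NULL` for the default grid.
#' @param q,n_samples As in [microstate_entropy()].
#' @param seed Seed used (identically) for each candidate's sampling, so
#'   the curve is smooth in `r` rather than jittered by sampling noise.
#' @return List with `radius` (selected) and `curve` (data frame of
#'   `radius`, `entropy`).
#' @export
select_radius <- function(y, candidates = NULL, q = 2L, n_samples = 10000L,
                          seed = 1L) {
  if (inherits(y, "display_series")) y <- y$y
  if (!length(y)) stop("series is empty")
  rng <- diff(range(y))
  if (is.null(candidates)) {
    candidates <- if (rng == 0) 0 else seq(0.01, 1, length.out = 50) * rng
  }
  candidates <- sort(unique(candidates))
  ent <- vapply(candidates, function(r)
    microstate_entropy(recurrence_matrix(y, r), q = q,
                       n_samples = n_samples, seed = seed),
    numeric(1))
  best <- candidates[which(ent >= max(ent) - 1e-12)[1]]  # smallest argmax
  list(radius = best, curve = data.frame(radius = candidates, entropy = ent))
}

#' Full RQA summary of a display series
#'
#' Selects the radius by entropy maximisation, builds the recurrence
#' matrix once, and computes the five consistency metrics: RR, DET, LAM,
#' microstate entropy and the selected radius. Higher RR and DET with
#' lower entropy read as a more consistent display.
#'
#' @param series A [display_series()] or numeric vector.
#' @param q,n_samples,seed As in [microstate_entropy()]; the same seed
#'   drives radius selection and the final entropy, so results are
#'   bit-reproducible.
#' @param l_min,v_min Minimum line lengths for DET and LAM.
#' @param radius Optional fixed radius, bypassing selection.
#' @return An object of class `rqa_metrics`: `rr`, `det`, `lam`, `mcentr`
#'   (nats), `radius`, `n`, plus the sampling parameters.
#' @export
rqa_summary <- function(series, q = 2L, n_samples = 10000L, seed = 1L,
                        l_min = 2L, v_min = 2L, radius = NULL) {
  y <- if (inherits(series, "display_series")) series$y else as.numeric(series)
  if (is.null(radius)) {
    sel <- select_radius(y, q = q, n_samples = n_samples, seed = seed)
    radius <- sel$radius
  }
  R <- recurrence_matrix(y, radius)
  structure(list(rr = recurrence_rate(R),
                 det = determinism(R, l_min),
                 lam = laminarity(R, v_min),
                 mcentr = microstate_entropy(R, q = q, n_samples = n_samples,
                                             seed = seed),
                 radius = radius, n = R$n,
                 q = q, n_samples_mc = n_samples, seed = seed),
            class = "rqa_metrics")
}

#' @export
print.rqa_metrics <- function(x, ...) {
  cat(sprintf(paste0("<rqa_metrics> n=%d  r=%.3g\n",
                     "  RR  %6.2f %%\n  DET %6.2f %%\n  LAM %6.2f %%\n",
                     "  MCEntr %.4f nats (q=%d, %d samples)\n"),
              x$n, x$radius, x$rr, x$det, x$lam, x$mcentr, x$q,
              x$n_samples_mc))
  invisible(x)
}

#' @export
as.data.frame.rqa_metrics <- function(x, ...) {
  data.frame(rr = x$rr, det = x$det, lam = x$lam, mcentr = x$mcentr,
             r_sel = x$radius, n = x$n)
}
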