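#' Binary colour mask of a frame
#'
#' A pixel is masked iff every channel lies inside the configured colour
#' range (inclusive). This is the first stage of the head tracker: with the
#' default range it isolates the males' red head plumage.
#'
#' @param frame A height x width x 3 RGB array with values in 0-255.
#' @param config A [tracker_config()].
#' @return A height x width logical matrix.
#' @export
color_mask <- function(frame, config = tracker_config()) {
  if (length(dim(frame)) != 3L || dim(frame)[3] < 3L)
    stop("`frame` must be an RGB array (height x width x 3)")
  lo <- config$color_lo; hi <- config$color_hi
  frame[, , 1] >= lo[1] & frame[, , 1] <= hi[1] &
    frame[, , 2] >= lo[2] & frame[, , 2] <= hi[2] &
    frame[, , 3] >= lo[3] & frame[, , 3] <= hi[3]
}

## Resolve the quadrant grid for a frame of the given size.
resolve_grid <- function(config, W, H) {
  if (!is.null(config$grid)) {
    g <- config$grid
    if (g[1] > W || g[2] > H) stop("quadrant grid larger than the frame")
    g
  } else {
    c(ceiling(W / config$cell_px), ceiling(H / config$cell_px))
  }
}

#' Per-quadrant colour coverage
#'
#' Divides the frame into a grid of quadrants and reports, for each, the
#' fraction of its pixels that are masked. Edge quadrants may be smaller
#' than the rest; the fraction always uses the actual cell area.
#'
#' @param mask Logical matrix from [color_mask()].
#' @param config A [tracker_config()]; its `grid` (or `cell_px`) defines the
#'   quadrants.
#' @return An `n_rows x n_cols` matrix of fractions in `[0, 1]`, with
#'   attributes `cell_x`/`cell_y` (quadrant centre coordinates in pixels)
#'   and `cell_w`/`cell_h`.
#' @export
quadrant_coverage <- function(mask, config = tracker_config()) {
  H <- nrow(mask); W <- ncol(mask)
  g <- resolve_grid(config, W, H)
  n_cols <- g[1]; n_rows <- g[2]
  cw <- ceiling(W / n_cols); ch <- ceiling(H / n_rows)
  rg <- pmin((seq_len(H) - 1L) %/% ch + 1L, n_rows)
  cg <- pmin((seq_len(W) - 1L) %/% cw + 1L, n_cols)
  counts <- t(rowsum(t(rowsum(mask + 0, rg)), cg))     # n_rows x n_cols
  areas <- outer(tabulate(rg, n_rows), tabulate(cg, n_cols))
  cov <- counts / areas
  ## pixel-centre coordinates of each quadrant
  cx <- vapply(seq_len(n_cols), function(j)
    mean(which(cg == j)), numeric(1))
  cy <- vapply(seq_len(n_rows), function(i)
    mean(which(rg == i)), numeric(1))
  structure(cov, cell_x = cx, cell_y = cy, cell_w = cw, cell_h = ch,
            class = c("quadrant_coverage", "matrix"))
}

## 8-connectivity labelling of a small logical grid (flood fill).
label_components <- function(det) {
  lab <- matrix(0L, nrow(det), ncol(det))
  nxt <- 0L
  idx <- which(det, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= nrow(det) && nj >= 1 && nj <= ncol(det) &&
            det[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

#' Detect males from quadrant coverages
#'
#' A quadrant registers when its coverage reaches `coverage_threshold`;
#' 8-connected registered quadrants are merged into a single detection at
#' their coverage-weighted centroid (in pixels), so one head straddling a
#' grid line still yields one male.
#'
#' @param coverages A [quadrant_coverage()] result.
#' @param config A [tracker_config()].
#' @return A data frame with one row per detection: `x`, `y`
#'   (coverage-weighted centroid, px), `n_cells` and `peak_coverage`.
#' @export
detect_males <- function(coverages, config = tracker_config()) {
  det <- coverages >= config$coverage_threshold
  if (!any(det))
    return(data.frame(x = numeric(0), y = numeric(0),
                      n_cells = integer(0), peak_coverage = numeric(0)))
  lab <- label_components(det)
  cx <- attr(coverages, "cell_x"); cy <- attr(coverages, "cell_y")
  out <- lapply(seq_len(max(lab)), function(l) {
    cells <- which(lab == l, arr.ind = TRUE)
    w <- coverages[cells]
    data.frame(x = sum(cx[cells[, 2]] * w) / sum(w),
               y = sum(cy[cells[, 1]] * w) / sum(w),
               n_cells = nrow(cells),
               peak_coverage = max(w))
  })
  do.call(rbind, out)
}

#' Edge-male vertical series from per-frame detections
#'
#' Per frame, the edge male is the detection at the extreme horizontal
#' position towards the female (when `female_column` is set, the detection
#' closest to her) or towards the configured dance side. Once a male is
#' tracked he is retained until another detection strictly passes him
#' horizontally (by more than `handoff_eps`); at that point tracking hands
#' off, mirroring the queueing of the cartwheel. Detection dropouts up to
#' `max_gap` frames are bridged by carrying the last position forward;
#' longer dropouts split the series and the longest segment is returned
#' with a warning.
#'
#' @param detections A list with one [detect_males()] data frame per frame.
#' @param config A [tracker_config()].
#' @param fps Source frame rate of `detections`.
#' @param meta Optional meta list stored on the series.
#' @return A [display_series()] at the source frame rate.
#' @export
edge_male_series <- function(detections, config = tracker_config(), fps = 30,
                             meta = list()) {
  n <- length(detections)
  has_det <- vapply(detections, nrow, integer(1)) > 0L
  if (!any(has_det)) stop("no frames contain any detection")
  if (mean(has_det) < 0.5)
    warning("fewer than 50% of frames contain a detection")

  ## edge score: larger = closer to the edge of the dance
  score_fun <- if (!is.null(config$female_column)) {
    fc <- config$female_column
    function(x) -abs(x - fc)
  } else {
    dir <- config$dance_direction
    if (dir == "auto") {
      xbar <- vapply(detections[has_det],
                     function(d) mean(d$x), numeric(1))
      dir <- if (length(xbar) > 1 && stats::median(diff(xbar)) < 0)
        "left" else "right"
    }
    if (dir == "left") function(x) -x else function(x) x
  }

  y <- rep(NA_real_, n)
  prev_x <- NA_real_
  gap <- 0L
  seg_id <- rep(NA_integer_, n)
  cur_seg <- 1L
  for (f in seq_len(n)) {
    d <- detections[[f]]
    if (nrow(d) == 0L) {
      gap <- gap + 1L
      if (gap <= config$max_gap && f > 1L && !is.na(y[f - 1L])) {
        y[f] <- y[f - 1L]          # bridge a short dropout
        seg_id[f] <- cur_seg
      } else if (gap == config$max_gap + 1L) {
        cur_seg <- cur_seg + 1L    # dropout too long: start a new segment
        prev_x <- NA_real_
      }
      next
    }
    gap <- 0L
    s <- score_fun(d$x)
    if (is.na(prev_x)) {
      pick <- which.max(s)
    } else {
      same <- which.min(abs(d$x - prev_x))
      best <- which.max(s)
      pick <- if (s[best] > s[same] + config$handoff_eps) best else same
    }
    y[f] <- d$y[pick]
    prev_x <- d$x[pick]
    seg_id[f] <- cur_seg
  }

  keep <- !is.na(seg_id)
  segs <- split(which(keep), seg_id[keep])
  if (length(segs) > 1L)
    warning("detection dropout longer than `max_gap` split the series; ",
            "returning the longest of ", length(segs), " segments")
  seg <- segs[[which.max(lengths(segs))]]
  seg <- seq(min(seg), max(seg))
  ys <- y[seg]
  ## interior NAs inside the chosen segment (bridged positions already
  ## carry values; leading NAs cannot occur within a segment)
  display_series(ys, fps = fps, t0 = (seg[1] - 1) / fps, meta = meta)
}

#' Downsample a display series
#'
#' Keeps every `factor`-th sample starting from the first, where `factor =
#' fps / target_fps` must be a whole number (e.g. 30 to 15 fps keeps every
#' second sample).
#'
#' @param series A [display_series()].
#' @param target_fps Target sampling rate.
#' @return A [display_series()] at `target_fps`.
#' @export
downsample_series <- function(series, target_fps = 15) {
  stopifnot(inherits(series, "display_series"))
  factor <- series$fps / target_fps
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("`target_fps` must divide the source fps (got factor ", factor, ")")
  factor <- as.integer(round(factor))
  display_series(series$y[seq(1L, length(series$y), by = factor)],
                 fps = target_fps, t0 = series$t0, meta = series$meta)
}

#' Track a scene (or frame list) into a display series
#'
#' Runs mask -> quadrant coverage -> detection -> edge-male series on every
#' frame and downsamples to `config$target_fps`. When `x` is a
#' `synthetic_scene` with a female, her column is passed to the edge rule
#' automatically unless the config already sets one.
#'
#' @param x A `synthetic_scene`, a list of RGB arrays, or a PNG directory
#'   path.
#' @param config A [tracker_config()].
#' @param fps Source frame rate (taken from the scene when available).
#' @param downsample Logical; downsample to `config$target_fps`.
#' @return A [display_series()].
#' @export
track_scene <- function(x, config = tracker_config(), fps = NULL,
                        downsample = TRUE) {
  if (is.character(x)) x <- read_frames(x)
  if (inherits(x, "synthetic_scene")) {
    if (is.null(config$female_column) && !is.null(x$female_column))
      config$female_column <- x$female_column
    if (is.null(fps)) fps <- x$params$fps
    frames <- x$frames
  } else {
    frames <- x
  }
  if (is.null(fps)) stop("`fps` must be given for raw frame input")
  detections <- lapply(frames, function(fr)
    detect_males(quadrant_coverage(color_mask(fr, config), config), config))
  series <- edge_male_series(detections, config, fps = fps)
  if (downsample && config$target_fps < fps)
    series <- downsample_series(series, config$target_fps)
  series
}

#' Calibrate the coverage threshold on labelled scenes
#'
#' Sweeps candidate coverage thresholds over scenes with known head
#' positions and counts, per frame, missed males (no detection within
#' `match_tol` pixels of a true head centre) plus spurious detections
#' (detections matching no head). Returns the threshold minimising the
#' total error, breaking ties towards the smallest threshold, together
#' with the full error curve — the operating-characteristic-style sweep
#' used to fix the 40% default.
#'
#' @param scenes A list of `synthetic_scene`s (or lists with `frames` and
#'   `head_centers`).
#' @param candidates Numeric thresholds to try.
#' @param config Base [tracker_config()]; its threshold is overridden per
#'   candidate.
#' @param match_tol Matching radius in pixels (default: 1.5 quadrant
#'   diagonals' worth, `3 * cell_px`).
#' @return A list with `best_threshold` and `curve` (data frame of
#'   `threshold`, `missed`, `spurious`, `error`).
#' @export
calibrate_threshold <- function(scenes,
                                candidates = c(0.30, 0.40, 0.50, 0.60, 0.70),
                                config = tracker_config(),
                                match_tol = 3 * config$cell_px) {
  if (!length(scenes)) stop("`scenes` must contain at least one scene")
  if (!length(candidates)) stop("`candidates` must be non-empty")
  ## precompute coverages once per frame; thresholding is then cheap
  covs <- lapply(scenes, function(sc)
    lapply(sc$frames, function(fr)
      quadrant_coverage(color_mask(fr, config), config)))

  eval_one <- function(th) {
    cfg <- config; cfg$coverage_threshold <- th
    missed <- 0L; spurious <- 0L
    for (s in seq_along(scenes)) {
      truth <- scenes[[s]]$head_centers
      for (f in seq_along(covs[[s]])) {
        d <- detect_males(covs[[s]][[f]], cfg)
        tx <- truth[f, , 1]; ty <- truth[f, , 2]
        unmatched_det <- rep(TRUE, nrow(d))
        for (m in seq_along(tx)) {
          if (!nrow(d)) { missed <- missed + 1L; next }
          dist <- sqrt((d$x - tx[m])^2 + (d$y - ty[m])^2)
          dist[!unmatched_det] <- Inf
          j <- which.min(dist)
          if (is.finite(dist[j]) && dist[j] <= match_tol)
            unmatched_det[j] <- FALSE
          else missed <- missed + 1L
        }
        spurious <- spurious + sum(unmatched_det)
      }
    }
    c(missed = missed, spurious = spurious)
  }

  res <- t(vapply(candidates, eval_one, c(missed = 0L, spurious = 0L)))
  curve <- data.frame(threshold = candidates,
                      missed = res[, "missed"],
                      spurious = res[, "spurious"],
                      error = res[, "missed"] + res[, "spurious"])
  ord <- order(curve$threshold)
  curve <- curve[ord, , drop = FALSE]
  best <- curve$threshold[which.min(curve$error)]  # ties -> smallest
  list(best_threshold = best, curve = curve)
}
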