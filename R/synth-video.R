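#' Render a synthetic display scene
#'
#' Rasterises a display into RGB frames the tracker can consume: a neutral
#' background, one blob per male (dark body plus a square head patch whose
#' colour sits inside the tracked red range), males in a horizontal row,
#' and an optional red-free female just beyond the active edge of the
#' dance. The edge male's head follows the trace from
#' [simulate_display_series()]; the other males hold the perch. Geometry is
#' simplified relative to a real cartwheel (queued males do not swap
#' places), which is irrelevant to the tracker because the series is read
#' only at the edge of the dance.
#'
#' @param params A [display_params()] object.
#' @param head_px Side (pixels) of the square head patch. The default 16 is
#'   twice the default tracker quadrant, guaranteeing that some quadrant is
#'   fully covered whatever the head's alignment.
#' @param head_color RGB triple of the head patch; must lie inside
#'   `[150,0,0]`-`[255,100,100]`.
#' @return A list of class `synthetic_scene`: `frames` (list of
#'   height x width x 3 integer arrays, 0-255), `truth_trace` (edge-male
#'   head-centre y per frame), `truth_events`, `head_centers` (an
#'   `n_frames x n_males x 2` array of head-centre x/y), `female_column`,
#'   and `params`.
#' @export
simulate_display_video <- function(params, head_px = 16L,
                                   head_color = c(200, 30, 30)) {
  stopifnot(inherits(params, "display_params"))
  p <- params
  if (any(head_color < c(150, 0, 0)) || any(head_color > c(255, 100, 100)))
    stop("`head_color` must lie inside the tracked red range")
  sim <- simulate_display_series(p)
  y_trace <- sim$series$y
  n_frames <- length(y_trace)
  W <- p$frame_size[1]; H <- p$frame_size[2]

  ## horizontal layout: males in a row, female (if any) one slot beyond the
  ## dance edge; slots must hold a head plus clearance so detections of
  ## neighbouring males never merge.
  n_slots <- p$n_males + as.integer(p$female_present)
  margin <- head_px
  spacing <- floor((W - 2 * margin) / max(n_slots - 1, 1))
  if (spacing < head_px + 8L)
    stop("frame too small to place ", p$n_males,
         " males (plus female) without overlap")
  xs <- margin + spacing * (seq_len(n_slots) - 1)
  if (p$dance_direction == "left") xs <- rev(xs)
  ## slot order runs from the back of the row towards the dance edge
  male_x <- xs[seq_len(p$n_males)]
  female_x <- if (p$female_present) xs[n_slots] else NULL
  edge_idx <- p$n_males   # the male adjacent to the edge/female flies

  bg <- c(205, 205, 195)
  body_col <- c(40, 60, 120)     # blue-black plumage, outside the red range
  female_col <- c(110, 120, 80)  # olive, no red head
  half <- head_px %/% 2L

  base_frame <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) base_frame[, , ch] <- bg[ch]

  paint <- function(fr, x0, x1, y0, y1, col) {
    x0 <- max(1L, x0); x1 <- min(W, x1); y0 <- max(1L, y0); y1 <- min(H, y1)
    if (x0 > x1 || y0 > y1) return(fr)
    for (ch in 1:3) fr[y0:y1, x0:x1, ch] <- col[ch]
    fr
  }
  draw_bird <- function(fr, cx, cy, head, col_head) {
    ## body hangs below the head
    fr <- paint(fr, cx - half + 2L, cx + half - 2L,
                cy + half, cy + half + head_px, body_col)
    if (!is.null(col_head))
      fr <- paint(fr, cx - half, cx + half - 1L,
                  cy - half, cy + half - 1L, col_head)
    else
      fr <- paint(fr, cx - half, cx + half - 1L,
                  cy - half, cy + half - 1L, female_col)
    fr
  }

  frames <- vector("list", n_frames)
  centers <- array(NA_real_, dim = c(n_frames, p$n_males, 2L))
  for (f in seq_len(n_frames)) {
    fr <- base_frame
    for (m in seq_len(p$n_males)) {
      cy <- if (m == edge_idx) as.integer(round(y_trace[f])) else
        as.integer(p$baseline_y)
      cy <- min(max(cy, half + 1L), H - head_px - half)
      fr <- draw_bird(fr, as.integer(male_x[m]), cy, head_px, head_color)
      centers[f, m, ] <- c(male_x[m], cy)
    }
    if (p$female_present)
      fr <- draw_bird(fr, as.integer(female_x), as.integer(p$baseline_y),
                      head_px, NULL)
    storage.mode(fr) <- "integer"
    frames[[f]] <- fr
  }

  structure(list(frames = frames,
                 truth_trace = centers[, edge_idx, 2],
                 truth_events = sim$events,
                 head_centers = centers,
                 female_column = female_x,
                 head_px = head_px,
                 params = p),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<synthetic_scene> %d frames (%dx%d), %d males%s\n",
              length(x$frames), d[2], d[1], x$params$n_males,
              if (x$params$female_present) " + female" else ""))
  invisible(x)
}

#' Write / read scene frames as a PNG directory
#'
#' Frames are written as zero-padded `frame_000001.png` files so a scene
#' can stand in for a decoded video clip on disk.
#'
#' @param scene A `synthetic_scene` (or any list of 0-255 RGB arrays in
#'   `$frames`).
#' @param dir Output directory, created if needed.
#' @return `write_frames` returns `dir` invisibly; `read_frames` returns a
#'   list of integer RGB arrays (0-255).
#' @export
write_frames <- function(scene, dir) {
  frames <- if (is.list(scene) && !is.null(scene$frames)) scene$frames else scene
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    a <- a[, , 1:3, drop = FALSE] * 255
    storage.mode(a) <- "integer"
    a
  })
}
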