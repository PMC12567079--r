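## Independent brute-force reference implementations used to validate the
## package. Deliberately naive: plain loops, no shared code with R/.

oracle_recurrence_matrix <- function(y, radius) {
  n <- length(y)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(y[i] - y[j]) <= radius) R[i, j] <- 1L
  R
}

oracle_rr <- function(R) {
  n <- nrow(R)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + R[i, j]
  100 * s / (n * n)
}

## maximal diagonal lines off the main diagonal, both triangles
oracle_diag_lengths <- function(R) {
  n <- nrow(R)
  out <- integer(0)
  for (k in c(seq(-(n - 1), -1), seq_len(n - 1))) {
    run <- 0L
    for (s in seq_len(n - abs(k))) {
      i <- if (k >= 0) s else s - k
      j <- if (k >= 0) s + k else s
      if (R[i, j] == 1L) run <- run + 1L
      else { if (run > 0L) out <- c(out, run); run <- 0L }
    }
    if (run > 0L) out <- c(out, run)
  }
  out
}

## maximal vertical lines, main-diagonal cell removed first
oracle_vert_lengths <- function(R) {
  n <- nrow(R)
  out <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      v <- if (i == j) 0L else R[i, j]
      if (v == 1L) run <- run + 1L
      else { if (run > 0L) out <- c(out, run); run <- 0L }
    }
    if (run > 0L) out <- c(out, run)
  }
  out
}

oracle_det <- function(R, l_min = 2L) {
  l <- oracle_diag_lengths(R)
  if (!length(l) || sum(l) == 0) return(0)
  100 * sum(l[l >= l_min]) / sum(l)
}

oracle_lam <- function(R, v_min = 2L) {
  l <- oracle_vert_lengths(R)
  if (!length(l) || sum(l) == 0) return(0)
  100 * sum(l[l >= v_min]) / sum(l)
}

## exact plug-in microstate entropy by full enumeration (q = 2)
oracle_microstate_entropy <- function(R) {
  n <- nrow(R)
  counts <- integer(16)
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    id <- 1L + R[i, j] + 2L * R[i + 1, j] + 4L * R[i, j + 1] +
      8L * R[i + 1, j + 1]
    counts[id] <- counts[id] + 1L
  }
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

## random symmetric binary matrix with unit diagonal
random_recurrence_like <- function(n, p = 0.3) {
  up <- matrix(stats::rbinom(n * n, 1L, p), n, n)
  up[lower.tri(up)] <- t(up)[lower.tri(up)]
  diag(up) <- 1L
  up
}

## brute-force per-cell pixel counts for quadrant coverage
oracle_quadrant_counts <- function(mask, cw, ch, n_cols, n_rows) {
  counts <- matrix(0, n_rows, n_cols)
  areas <- matrix(0, n_rows, n_cols)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    r <- min((i - 1) %/% ch + 1, n_rows)
    c <- min((j - 1) %/% cw + 1, n_cols)
    counts[r, c] <- counts[r, c] + mask[i, j]
    areas[r, c] <- areas[r, c] + 1
  }
  counts / areas
}

## naive peak counter: strict local maxima with prominence computed by
## scanning outwards to the nearest higher point
oracle_peak_count <- function(x, min_prom) {
  n <- length(x)
  count <- 0L
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] > x[i + 1])) next
    lmin <- x[i]; j <- i - 1
    while (j >= 1 && x[j] < x[i]) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- x[i]; j <- i + 1
    while (j <= n && x[j] < x[i]) { rmin <- min(rmin, x[j]); j <- j + 1 }
    if (x[i] - max(lmin, rmin) >= min_prom) count <- count + 1L
  }
  count
}

## a tiny hand-built labelled scene for calibration tests: heads are
## cell-aligned rectangles covering a chosen fraction of one quadrant,
## plus an optional fainter spurious patch
make_calibration_scene <- function(n_frames = 5, cell = 10L,
                                   head_frac = 0.45, spur_frac = 0,
                                   W = 60L, H = 40L) {
  head_px_n <- round(head_frac * cell * cell)
  hw <- cell - 3L; hh <- ceiling(head_px_n / hw)
  head_cols <- c(200L, 40L, 40L)
  frames <- vector("list", n_frames)
  centers <- array(NA_real_, dim = c(n_frames, 1L, 2L))
  for (f in seq_len(n_frames)) {
    fr <- array(180L, dim = c(H, W, 3L))
    ## head inside the quadrant with rows 11..20, cols 21..30
    r0 <- 11L; c0 <- 21L
    px <- 0L
    for (i in 0:(hh - 1L)) for (j in 0:(hw - 1L)) {
      if (px < head_px_n) {
        for (ch in 1:3) fr[r0 + i, c0 + j, ch] <- head_cols[ch]
        px <- px + 1L
      }
    }
    centers[f, 1L, ] <- c(c0 + hw / 2, r0 + hh / 2)
    if (spur_frac > 0) {
      spn <- round(spur_frac * cell * cell)
      sw <- cell - 3L; sh <- ceiling(spn / sw)
      px <- 0L
      for (i in 0:(sh - 1L)) for (j in 0:(sw - 1L)) {
        if (px < spn) {
          for (ch in 1:3) fr[31L + i, 41L + j, ch] <- head_cols[ch]
          px <- px + 1L
        }
      }
    }
    frames[[f]] <- fr
  }
  list(frames = frames, head_centers = centers)
}
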