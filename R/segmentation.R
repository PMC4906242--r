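#' Re-align a movie for stage drift
#'
#' Estimates a per-frame integer (x, y) translation relative to a reference
#' frame by cross-correlation (FFT-based, mean-subtracted) and shifts each
#' frame back.  Frames whose estimated shift exceeds `max_shift` are flagged
#' and left unshifted.  Vacated pixels are filled with the frame median.
#'
#' @param movie numeric array `[H, W, T]`.
#' @param max_shift maximum plausible shift (pixels).
#' @param reference reference frame index (default 1, i.e. the first
#'   pre-stimulation frame).
#' @return A list with `movie` (aligned array) and `shifts` (data.frame:
#'   frame, dx, dy, flagged).
#' @export
realign <- function(movie, max_shift = 5L, reference = 1L) {
  stopifnot(length(dim(movie)) == 3, dim(movie)[3] >= 2)
  H <- dim(movie)[1]; W <- dim(movie)[2]; TT <- dim(movie)[3]
  ref <- movie[, , reference]
  Fr <- stats::fft(ref - mean(ref))
  dx <- integer(TT); dy <- integer(TT); flagged <- logical(TT)
  out <- movie
  for (t in seq_len(TT)) {
    if (t == reference) next
    fr <- movie[, , t]
    cc <- Re(stats::fft(Fr * Conj(stats::fft(fr - mean(fr))),
                        inverse = TRUE))
    k <- which.max(cc)
    pr <- ((k - 1) %% H)
    pc <- ((k - 1) %/% H)
    # map wrap-around indices to signed shifts of the frame vs reference
    sy <- if (pr > H / 2) pr - H else pr
    sx <- if (pc > W / 2) pc - W else pc
    # with this conj convention a frame displaced by +d peaks at -d
    ey <- -sy; ex <- -sx
    dy[t] <- ey; dx[t] <- ex
    if (abs(ey) > max_shift || abs(ex) > max_shift) {
      flagged[t] <- TRUE
      dy[t] <- 0L; dx[t] <- 0L
      next
    }
    if (ey != 0 || ex != 0)
      out[, , t] <- shift_frame(fr, -ey, -ex)
  }
  list(movie = out,
       shifts = data.frame(frame = seq_len(TT), dx = dx, dy = dy,
                           flagged = flagged))
}

#' Pixelwise dF response map
#'
#' Computes, per pixel, the baseline fluorescence (mean over pre-stimulation
#' frames), the peak during the first AP train (maximum of a moving average,
#' which suppresses single-frame noise spikes), and their difference
#' `dF = F_peak - F_baseline`.
#'
#' @param movie numeric array `[H, W, T]`.
#' @param protocol an [stim_protocol()].
#' @param smooth moving-average window (frames) for the peak (default 3).
#' @return A list of class `svc_response_map` with matrices `f_baseline`,
#'   `f_peak`, `df`, and the frame windows used.
#' @export
response_map <- function(movie, protocol, smooth = 3L) {
  validate_protocol(protocol)
  ft <- frame_times(protocol)[seq_len(dim(movie)[3])]
  w <- train_windows(protocol)
  base_idx <- which(ft < w[1, 1])
  train_idx <- which(ft >= w[1, 1] & ft <= w[1, 2])
  if (length(base_idx) < 3) stop("need >= 3 pre-stimulation frames")
  if (length(train_idx) < 3) stop("need >= 3 first-train frames")
  if (max(train_idx) > dim(movie)[3])
    stop("protocol window outside movie duration")
  H <- dim(movie)[1]; W <- dim(movie)[2]
  f_base <- apply(movie[, , base_idx, drop = FALSE], c(1, 2), mean)
  # moving average along time within the train window
  tr <- movie[, , train_idx, drop = FALSE]
  nt <- length(train_idx)
  nw <- nt - smooth + 1
  f_peak <- matrix(-Inf, H, W)
  run <- array(0, c(H, W))
  for (s in seq_len(nw)) {
    run[] <- 0
    for (k in s:(s + smooth - 1)) run <- run + tr[, , k]
    run <- run / smooth
    f_peak <- pmax(f_peak, run)
  }
  structure(list(f_baseline = f_base, f_peak = f_peak,
                 df = f_peak - f_base,
                 baseline_frames = base_idx, train_frames = train_idx,
                 smooth = smooth),
            class = "svc_response_map")
}

# Two-pass 4-connected component labeling with union-find.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nextlab <- 0L
  for (c in seq_len(W)) {
    for (r in seq_len(H)) {
      if (!mask[r, c]) next
      up <- if (r > 1) lab[r - 1, c] else 0L
      left <- if (c > 1) lab[r, c - 1] else 0L
      if (up == 0L && left == 0L) {
        nextlab <- nextlab + 1L
        parent[nextlab] <- nextlab
        lab[r, c] <- nextlab
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        root <- min(ru, rl)
        parent[ru] <- root; parent[rl] <- root
        lab[r, c] <- root
      } else {
        lab[r, c] <- max(up, left)
      }
    }
  }
  if (nextlab == 0L) return(lab)
  # resolve equivalences and renumber in raster order of first occurrence
  roots <- vapply(seq_len(nextlab), find, integer(1))
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  ids <- unique(lab[lab > 0L])       # column-major raster order
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Disk offsets of radius r, grouped by squared distance (ascending).
disk_rings <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  d$d2 <- d$dy^2 + d$dx^2
  d <- d[d$d2 <= r^2 & d$d2 > 0, ]
  split(d[, c("dy", "dx")], factor(d$d2, levels = sort(unique(d$d2))))
}

# Dilate a label image by a disk, assigning contested pixels to the nearest
# original component (ties -> lower label id).  Never merges labels.
dilate_labels <- function(lab, radius) {
  if (radius <= 0) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  out <- lab
  dist_claimed <- matrix(Inf, H, W)
  dist_claimed[lab > 0L] <- 0
  for (ring in disk_rings(radius)) {
    prop <- matrix(0L, H, W)        # best (lowest) label proposal this ring
    d2 <- ring$dy[1]^2 + ring$dx[1]^2
    for (i in seq_len(nrow(ring))) {
      dy <- ring$dy[i]; dx <- ring$dx[i]
      tr <- (1 + max(0, dy)):(H + min(0, dy))
      tc <- (1 + max(0, dx)):(W + min(0, dx))
      sr <- tr - dy; sc <- tc - dx
      src <- lab[sr, sc, drop = FALSE]
      tgt <- prop[tr, tc, drop = FALSE]
      take <- src > 0L & (tgt == 0L | src < tgt)
      tgt[take] <- src[take]
      prop[tr, tc] <- tgt
    }
    claim <- prop > 0L & dist_claimed > d2 & out == 0L
    out[claim] <- prop[claim]
    dist_claimed[claim] <- d2
  }
  out
}

#' Segment responsive boutons from a dF response map
#'
#' Binarizes the relative response (`dF >= threshold * F_baseline`), labels
#' 4-connected components, discards components whose mean relative response
#' falls below `min_rel_df`, dilates each surviving component by a disk
#' (contested pixels go to the nearest original component; ties to the lower
#' label id), and finally size-gates the dilated labels.
#'
#' Both cuts are relative to baseline, which makes the segmentation
#' invariant to a global intensity scale.
#'
#' @param rmap an [response_map()] result.
#' @param threshold pixel binarization cut as a fraction of baseline.
#' @param min_rel_df minimum component-mean relative response (default 0.05,
#'   i.e. components responding below 5% are excluded).
#' @param dilation_radius disk radius in pixels (default 1).
#' @param size_gate `(A_min, A_max)` areas in pixels applied after dilation.
#' @param baseline_floor floor applied to the per-pixel baseline before
#'   dividing: `"median"` (default) clamps at the image-median baseline so
#'   that shot-noise dips in dark pixels do not lower the threshold bar;
#'   a number gives an absolute floor; `0` disables.  The floor scales with
#'   the image, preserving scale invariance.
#' @return A list of class `svc_boutons` with `labels` (integer label
#'   image), `table` (data.frame: label, area_px, centroid_row,
#'   centroid_col, 0-based), and the parameters used.
#' @export
segment <- function(rmap, threshold = 0.5, min_rel_df = 0.05,
                    dilation_radius = 1L, size_gate = c(4, 150),
                    baseline_floor = "median") {
  stopifnot(inherits(rmap, "svc_response_map"))
  if (threshold <= 0) stop("threshold must be > 0")
  if (size_gate[1] > size_gate[2]) stop("invalid size gate: A_min > A_max")
  if (!all(is.finite(rmap$df))) stop("response map must be finite")
  eps <- .Machine$double.eps
  floor_val <- if (identical(baseline_floor, "median"))
    stats::median(rmap$f_baseline) else as.numeric(baseline_floor)
  base <- pmax(rmap$f_baseline, floor_val, eps)
  mask <- rmap$df >= threshold * base
  lab <- label_components(mask)
  if (max(lab) > 0 && min_rel_df > 0) {
    rel <- rmap$df / base
    keep <- vapply(seq_len(max(lab)), function(l)
      mean(rel[lab == l]) >= min_rel_df, logical(1))
    drop <- which(!keep)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  lab <- dilate_labels(lab, dilation_radius)
  # size gate after dilation
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0L])
    bad <- which(areas < size_gate[1] | areas > size_gate[2])
    if (length(bad)) lab[lab %in% bad] <- 0L
  }
  # renumber surviving labels in raster order
  ids <- unique(lab[lab > 0L])
  if (length(ids)) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  n <- if (length(ids)) length(ids) else 0L
  tab <- if (n > 0) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[lab > 0L]
    data.frame(
      label = seq_len(n),
      area_px = as.integer(tabulate(l, n)),
      centroid_row = as.numeric(tapply(idx[, 1], l, mean)) - 1,
      centroid_col = as.numeric(tapply(idx[, 2], l, mean)) - 1)
  } else {
    data.frame(label = integer(0), area_px = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0))
  }
  structure(list(labels = lab, table = tab, threshold = threshold,
                 min_rel_df = min_rel_df, dilation_radius = dilation_radius,
                 size_gate = size_gate),
            class = "svc_boutons")
}

#' Write a bouton map to disk
#'
#' Writes the label image as a 16-bit TIFF and the per-label table as CSV.
#'
#' @param boutons an `svc_boutons` object from [segment()].
#' @param tiff_path label image output path.
#' @param csv_path per-label table output path.
#' @return Invisibly, the two paths.
#' @export
write_bouton_map <- function(boutons, tiff_path, csv_path) {
  write_tiff(array(boutons$labels, c(dim(boutons$labels), 1)), tiff_path)
  utils::write.csv(boutons$table, csv_path, row.names = FALSE)
  invisible(c(tiff_path, csv_path))
}
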