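# TraceSet container: per-bouton time series with provenance and QC state.
new_traces <- function(time, norm, raw, meta, f_ref) {
  stopifnot(nrow(norm) == nrow(meta), ncol(norm) == length(time))
  structure(list(time = time, norm = norm, raw = raw, meta = meta,
                 f_ref = f_ref),
            class = "svc_traces")
}

#' @export
print.svc_traces <- function(x, ...) {
  cat("svc_traces:", nrow(x$norm), "boutons x", length(x$time), "frames;",
      sum(x$meta$qc_status == "kept"), "kept\n")
  invisible(x)
}

#' Extract NH4Cl-normalized per-bouton traces
#'
#' For each label, the raw trace is the mean pixel intensity over the label
#' at each frame.  Traces are divided by the mean of the last
#' `norm_frames` post-NH4Cl frames, which reveals the total reporter pool
#' and cancels expression differences between boutons.  Boutons whose
#' post-NH4Cl signal does not exceed their baseline are marked
#' `excluded:nh4cl_invalid`.
#'
#' @param movie numeric array `[H, W, T]` (aligned).
#' @param boutons an `svc_boutons` from [segment()].
#' @param protocol an [stim_protocol()] with `nh4cl_time` set.
#' @param norm_frames number of terminal post-NH4Cl frames to average.
#' @param prep_id,field_id,group provenance labels stored with each trace.
#' @return An `svc_traces` object.
#' @export
extract_traces <- function(movie, boutons, protocol, norm_frames = 5L,
                           prep_id = "prep01", field_id = "field001",
                           group = "ctrl") {
  validate_protocol(protocol)
  if (!is.finite(protocol$nh4cl_time))
    stop("protocol must include nh4cl_time for normalization")
  lab <- boutons$labels
  n <- max(lab)
  if (n == 0) stop("bouton map has no labels")
  TT <- dim(movie)[3]
  ft <- frame_times(protocol)[seq_len(TT)]
  post <- which(ft >= protocol$nh4cl_time)
  if (length(post) < norm_frames)
    stop("NH4Cl window shorter than norm_frames")
  idx <- which(lab > 0L)
  l <- lab[idx]
  if (any(tabulate(l, n) == 0)) stop("label with 0 pixels")
  raw <- matrix(0, n, TT)
  flat <- matrix(movie, ncol = TT)
  counts <- tabulate(l, n)
  for (t in seq_len(TT))
    raw[, t] <- rowsum(flat[idx, t], l)[, 1] / counts
  norm_idx <- utils::tail(post, norm_frames)
  f_ref <- rowMeans(raw[, norm_idx, drop = FALSE])
  base_idx <- which(ft < protocol$train_onsets[1])
  base <- rowMeans(raw[, base_idx, drop = FALSE])
  qc <- ifelse(f_ref <= base, "excluded:nh4cl_invalid", "kept")
  normd <- raw / f_ref
  meta <- data.frame(bouton_id = sprintf("%s_b%03d", field_id, seq_len(n)),
                     prep_id = prep_id, field_id = field_id, group = group,
                     qc_status = qc, stringsAsFactors = FALSE)
  new_traces(time = ft, norm = normd, raw = raw, meta = meta, f_ref = f_ref)
}

#' Baseline-drift quality filter
#'
#' Excludes traces whose baseline drifts between the two stimulations or
#' after Baf application: a bouton is marked `excluded:baseline_drift` when
#' the difference of median baselines (pre-train-2 vs pre-train-1) exceeds
#' `drift_tol`, or when the fitted linear drift over the post-Baf segment,
#' accumulated over the segment duration, exceeds `drift_tol`.
#'
#' @param traces an `svc_traces`.
#' @param protocol a two-train [stim_protocol()].
#' @param drift_tol tolerance in normalized units (default 0.10).
#' @return The `svc_traces` with updated `qc_status`.
#' @export
qc_filter <- function(traces, protocol, drift_tol = 0.10) {
  validate_protocol(protocol)
  if (length(protocol$train_onsets) < 2)
    stop("qc_filter requires a two-train protocol")
  ft <- traces$time
  on1 <- sort(protocol$train_onsets)[1]
  on2 <- sort(protocol$train_onsets)[2]
  pre1 <- which(ft < on1)
  baf <- if (is.finite(protocol$baf_time)) protocol$baf_time else on2 - 30
  pre2 <- which(ft >= baf & ft < on2)
  if (length(pre2) < 2) pre2 <- utils::tail(which(ft < on2), 5)
  norm <- traces$norm
  med1 <- apply(norm[, pre1, drop = FALSE], 1, stats::median)
  med2 <- apply(norm[, pre2, drop = FALSE], 1, stats::median)
  jump <- abs(med2 - med1) > drift_tol
  # OLS slope over the post-Baf pre-train-2 segment, scaled by its duration
  tt <- ft[pre2]
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slope <- as.vector(norm[, pre2, drop = FALSE] %*% tc) / denom
  ramp <- abs(slope) * (max(tt) - min(tt)) > drift_tol
  bad <- (jump | ramp) & traces$meta$qc_status == "kept"
  traces$meta$qc_status[bad] <- "excluded:baseline_drift"
  traces
}

# 6-point OLS slope utility; y is a matrix [n x k] of in-window values,
# tt the frame times. Returns slope (/s) and R^2 per row.
ols_slope <- function(y, tt) {
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slope <- as.vector(y %*% tc) / denom
  yc <- y - rowMeans(y)
  ssr <- slope^2 * denom
  sst <- rowSums(yc^2)
  r2 <- ifelse(sst > 0, ssr / sst, NA_real_)
  data.frame(slope = slope, r2 = r2)
}

# Frames at-or-after an onset time
frames_from <- function(time, onset) which(time >= onset - 1e-9)

#' Exocytic rate from the Baf-train rise
#'
#' OLS slope of the normalized trace over the first `n_points` frames
#' starting at the first frame at-or-after the train onset.  With Baf
#' active, the rise reports cumulative exocytosis only, so this slope is the
#' exocytic rate in normalized dF per second.  Without Baf (`train = 1`),
#' the same window approximates the exocytic rate minus concurrent
#' endocytosis.
#'
#' @param traces an `svc_traces` or a numeric matrix `[n x T]`.
#' @param protocol an [stim_protocol()].
#' @param train which train window to fit (default 2, the Baf train).
#' @param n_points number of fitted frames (default 6).
#' @param time frame times, required when `traces` is a bare matrix.
#' @return data.frame with `slope` (per second) and `r2` per bouton.
#' @export
exo_rate <- function(traces, protocol, train = 2L, n_points = 6L,
                     time = NULL) {
  y <- if (inherits(traces, "svc_traces")) traces$norm else
    if (is.matrix(traces)) traces else matrix(traces, 1)
  if (is.null(time))
    time <- if (inherits(traces, "svc_traces")) traces$time else
      frame_times(protocol)[seq_len(ncol(y))]
  onset <- sort(protocol$train_onsets)[min(train, length(protocol$train_onsets))]
  win <- frames_from(time, onset)
  dur_idx <- win[time[win] <= onset + protocol$train_n_aps[train] /
                   protocol$train_freq + 1e-9]
  if (length(dur_idx) < n_points)
    stop("fewer than ", n_points, " in-window frames")
  sel <- dur_idx[seq_len(n_points)]
  ols_slope(y[, sel, drop = FALSE], time[sel])
}

#' Cumulative endocytosis trace by train subtraction
#'
#' Aligns the first-train and Baf-train responses at their respective train
#' onsets (after subtracting each segment's pre-onset baseline frame level)
#' and subtracts: `endo(t) = baf(t) - first(t)`.  Because the Baf trace
#' accumulates exocytosis only while the first trace additionally loses
#' re-acidified reporter, the difference is a measure of cumulative
#' endocytosis.  Windows are truncated to the shorter usable span.
#'
#' @param traces an `svc_traces` (two-train protocol).
#' @param protocol an [stim_protocol()].
#' @param window_s analysis window length after onset (s); default extends
#'   to the longest span available for both trains.
#' @return A list with `time` (seconds from onset) and `endo`
#'   (matrix `[n x k]`), plus the component matrices `first` and `baf`.
#' @export
endo_trace <- function(traces, protocol, window_s = NULL) {
  stopifnot(inherits(traces, "svc_traces"))
  if (length(protocol$train_onsets) < 2)
    stop("endo_trace requires a two-train protocol")
  ft <- traces$time
  on <- sort(protocol$train_onsets)
  i1 <- frames_from(ft, on[1]); i2 <- frames_from(ft, on[2])
  # usable spans: up to next event (train 2 / NH4Cl)
  lim1 <- if (is.finite(protocol$baf_time)) protocol$baf_time else on[2]
  lim2 <- if (is.finite(protocol$nh4cl_time)) protocol$nh4cl_time else
    max(ft) + protocol$frame_interval
  i1 <- i1[ft[i1] < lim1]
  i2 <- i2[ft[i2] < lim2]
  k <- min(length(i1), length(i2))
  if (!is.null(window_s))
    k <- min(k, sum(ft[i1[seq_len(k)]] - on[1] <= window_s + 1e-9))
  i1 <- i1[seq_len(k)]; i2 <- i2[seq_len(k)]
  pre_of <- function(i0) {
    sel <- max(1, i0 - 3):max(1, i0 - 1)
    apply(traces$norm[, sel, drop = FALSE], 1, stats::median)
  }
  b1 <- pre_of(i1[1])
  b2 <- pre_of(i2[1])
  first <- traces$norm[, i1, drop = FALSE] - b1
  baf <- traces$norm[, i2, drop = FALSE] - b2
  list(time = ft[i1] - on[1], endo = baf - first, first = first, baf = baf)
}

#' Endocytic rate from the difference trace
#'
#' Endocytosis lags exocytosis and becomes measurable towards the end of an
#' AP train, so the 6-point linear fit starts `onset_offset_frames` after
#' the train onset (default 9 frames, i.e. 18 s into a 30 s train at
#' 0.5 Hz).
#'
#' @param endo result of [endo_trace()], or a matrix of cumulative
#'   endocytosis with attribute-free rows (then supply `time`).
#' @param protocol an [stim_protocol()].
#' @param onset_offset_frames frames to skip after onset (default 9).
#' @param n_points fitted frames (default 6).
#' @param time seconds-from-onset vector when `endo` is a bare matrix.
#' @return data.frame with `slope` (per second) and `r2` per bouton.
#' @export
endo_rate <- function(endo, protocol, onset_offset_frames = 9L,
                      n_points = 6L, time = NULL) {
  if (is.list(endo) && !is.null(endo$endo)) {
    y <- endo$endo; time <- endo$time
  } else {
    y <- if (is.matrix(endo)) endo else matrix(endo, 1)
    if (is.null(time)) time <- frame_times(protocol)[seq_len(ncol(y))]
  }
  sel <- seq(onset_offset_frames + 1L, length.out = n_points)
  if (max(sel) > ncol(y)) stop("insufficient frames for endocytic fit")
  ols_slope(y[, sel, drop = FALSE], time[sel])
}

#' Releasable-pool plateau under a depleting stimulus
#'
#' Under a stimulus strong enough to deplete releasable vesicles (with Baf),
#' the normalized trace plateaus at the releasable-pool fraction.  The
#' plateau is the mean over the last `k` in-protocol frames before NH4Cl;
#' if the trailing slope still exceeds `slope_tol` the estimate is flagged
#' as not plateaued (but still reported).
#'
#' @param traces an `svc_traces` or numeric matrix.
#' @param protocol a depletion [stim_protocol()].
#' @param k number of trailing frames averaged (default 10).
#' @param slope_tol absolute trailing slope (per s) above which the trace is
#'   flagged (default 1e-3).
#' @param time frame times when `traces` is a bare matrix.
#' @return data.frame with `plateau` and logical `plateaued` per bouton.
#' @export
pool_plateau <- function(traces, protocol, k = 10L, slope_tol = 1e-3,
                         time = NULL) {
  y <- if (inherits(traces, "svc_traces")) traces$norm else
    if (is.matrix(traces)) traces else matrix(traces, 1)
  if (is.null(time))
    time <- if (inherits(traces, "svc_traces")) traces$time else
      frame_times(protocol)[seq_len(ncol(y))]
  lim <- if (is.finite(protocol$nh4cl_time)) protocol$nh4cl_time else
    max(time) + 1
  sel <- utils::tail(which(time < lim), k)
  seg <- y[, sel, drop = FALSE]
  sl <- ols_slope(seg, time[sel])
  data.frame(plateau = rowMeans(seg), plateaued = abs(sl$slope) <= slope_tol)
}

#' Calcium response summaries
#'
#' Per-bouton peak response normalized to the ionomycin-saturated maximum,
#' `(F_peak - F_baseline) / (F_iono - F_baseline)`, plus the empirical
#' cumulative distribution of peaks per group on a shared grid.  Boutons
#' with `F_iono <= F_baseline` are excluded.
#'
#' @param traces an `svc_traces` of calcium traces (raw or normalized).
#' @param protocol an [stim_protocol()] with `ionomycin_time`.
#' @param grid_n number of CDF grid points.
#' @return A list of class `svc_ca_summary` with `peaks` (data.frame incl.
#'   provenance) and `cdf` (long data.frame: group, x, p).
#' @export
ca_summaries <- function(traces, protocol, grid_n = 200L) {
  stopifnot(inherits(traces, "svc_traces"))
  if (!is.finite(protocol$ionomycin_time))
    stop("protocol must include ionomycin_time")
  ft <- traces$time
  w <- train_windows(protocol)
  base_idx <- which(ft < w[1, 1])
  iono_idx <- which(ft >= protocol$ionomycin_time)
  stim_idx <- which(ft >= min(w[, 1]) & ft < protocol$ionomycin_time)
  y <- traces$norm
  f0 <- rowMeans(y[, base_idx, drop = FALSE])
  fi <- rowMeans(y[, iono_idx, drop = FALSE])
  ok <- fi > f0
  peak <- apply(y[, stim_idx, drop = FALSE], 1, max)
  npk <- (peak - f0) / (fi - f0)
  peaks <- data.frame(traces$meta, peak_norm = ifelse(ok, npk, NA_real_))
  grid <- seq(0, max(npk[ok], 1), length.out = grid_n)
  cdfs <- lapply(split(npk[ok], traces$meta$group[ok]), function(v)
    stats::ecdf(v)(grid))
  cdf <- do.call(rbind, lapply(names(cdfs), function(g)
    data.frame(group = g, x = grid, p = cdfs[[g]])))
  structure(list(peaks = peaks, cdf = cdf, n_excluded = sum(!ok)),
            class = "svc_ca_summary")
}

#' Percent inhibition between two group means
#'
#' `100 * (1 - mean_condition / mean_control)`.  Inputs are group-level
#' mean rates, typically mixed-model estimated means.
#'
#' @param mean_control control group mean (> 0).
#' @param mean_condition condition group mean.
#' @return Percentage inhibition (positive = condition slower).
#' @examples
#' percent_inhibition(1.0, 0.27)   # 73
#' @export
percent_inhibition <- function(mean_control, mean_condition) {
  if (!is.finite(mean_control) || mean_control <= 0)
    stop("mean_control must be positive")
  100 * (1 - mean_condition / mean_control)
}

#' Per-bouton rate table
#'
#' Convenience wrapper assembling the unit of statistical analysis: one row
#' per kept bouton with exocytic rate (Baf train), endocytic rate
#' (difference trace), response amplitudes and fit diagnostics.  Column
#' semantics are documented in
#' `system.file("extdata/rate_table_columns.csv", package = "svcycle")`.
#'
#' @param traces an `svc_traces` after [qc_filter()].
#' @param protocol a two-train [stim_protocol()].
#' @param onset_offset_frames passed to [endo_rate()].
#' @param n_points frames per linear fit.
#' @return data.frame (class `svc_rate_table`) with provenance columns and
#'   `exo_rate`, `exo_r2`, `endo_rate`, `endo_r2`, `exo_amplitude`,
#'   `net_amplitude`.
#' @export
rate_table <- function(traces, protocol, onset_offset_frames = 9L,
                       n_points = 6L) {
  ex <- exo_rate(traces, protocol, train = 2L, n_points = n_points)
  et <- endo_trace(traces, protocol)
  en <- endo_rate(et, protocol, onset_offset_frames = onset_offset_frames,
                  n_points = n_points)
  out <- data.frame(traces$meta,
                    exo_rate = ex$slope, exo_r2 = ex$r2,
                    endo_rate = en$slope, endo_r2 = en$r2,
                    exo_amplitude = apply(et$baf, 1, max),
                    net_amplitude = apply(et$first, 1, max))
  out <- out[out$qc_status == "kept", ]
  class(out) <- c("svc_rate_table", "data.frame")
  out
}
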