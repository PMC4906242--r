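#' Stimulation protocol
#'
#' Describes the acquisition and field-stimulation timeline of a time-lapse
#' experiment: frame interval, action-potential (AP) train onsets and sizes,
#' and the times at which bafilomycin (Baf), NH4Cl, or ionomycin are added.
#'
#' The default protocol is the standard two-train paradigm: frames every 2 s
#' (0.5 Hz), a pre-stimulation baseline, two consecutive trains of 300 APs at
#' 10 Hz separated by ~5 min of recovery, Baf added 30 s before the second
#' train, and 50 mM NH4Cl at the end of the series to reveal the total
#' reporter pool.
#'
#' @param frame_interval seconds between frames (default 2, i.e. 0.5 Hz).
#' @param train_onsets numeric vector of train onset times (s).
#' @param train_n_aps integer vector, number of APs per train.
#' @param train_freq stimulation frequency in Hz (scalar, shared by trains).
#' @param baf_time time of Baf addition (s), or `NA` if absent.
#' @param nh4cl_time time of NH4Cl addition (s), or `NA` if absent.
#' @param ionomycin_time time of ionomycin addition (s), or `NA` if absent.
#' @param total_duration total acquisition time (s).
#' @return An object of class `svc_protocol`.
#' @examples
#' p <- stim_protocol()
#' train_windows(p)
#' @export
stim_protocol <- function(frame_interval = 2,
                          train_onsets = c(20, 350),
                          train_n_aps = c(300, 300),
                          train_freq = 10,
                          baf_time = 320,
                          nh4cl_time = 400,
                          ionomycin_time = NA_real_,
                          total_duration = 420) {
  p <- structure(list(
    frame_interval = as.numeric(frame_interval),
    train_onsets = as.numeric(train_onsets),
    train_n_aps = as.numeric(train_n_aps),
    train_freq = as.numeric(train_freq),
    baf_time = as.numeric(baf_time),
    nh4cl_time = as.numeric(nh4cl_time),
    ionomycin_time = as.numeric(ionomycin_time),
    total_duration = as.numeric(total_duration)
  ), class = "svc_protocol")
  validate_protocol(p)
  p
}

#' Single-train pool-depletion protocol
#'
#' Convenience constructor for the depletion paradigm: one long train
#' (default 1200 APs at 10 Hz) under Baf, used to estimate the total
#' releasable pool from the trace plateau.
#'
#' @param n_aps number of APs in the train.
#' @param freq stimulation frequency (Hz).
#' @param frame_interval seconds between frames.
#' @param baseline pre-stimulation baseline duration (s).
#' @param post post-train duration before NH4Cl (s).
#' @return An `svc_protocol`.
#' @export
depletion_protocol <- function(n_aps = 1200, freq = 10, frame_interval = 2,
                               baseline = 20, post = 60) {
  dur <- n_aps / freq
  stim_protocol(frame_interval = frame_interval,
                train_onsets = baseline,
                train_n_aps = n_aps,
                train_freq = freq,
                baf_time = baseline - 10,
                nh4cl_time = baseline + dur + post,
                total_duration = baseline + dur + post + 20)
}

#' Train windows of a protocol
#'
#' @param protocol an `svc_protocol`.
#' @return A two-column matrix (onset, offset) in seconds, one row per train.
#' @export
train_windows <- function(protocol) {
  on <- protocol$train_onsets
  off <- on + protocol$train_n_aps / protocol$train_freq
  cbind(onset = on, offset = off)
}

#' Frame times of a protocol
#'
#' @param protocol an `svc_protocol`.
#' @return Numeric vector of frame acquisition times, starting at 0.
#' @export
frame_times <- function(protocol) {
  seq(0, protocol$total_duration, by = protocol$frame_interval)
}

#' Validate a stimulation protocol
#'
#' Checks the structural invariants: train windows are disjoint and inside
#' the acquisition, Baf (when present) precedes the second train, and
#' NH4Cl/ionomycin (when present) follow all trains.
#'
#' @param p an `svc_protocol`.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "svc_protocol"))
  if (!is.finite(p$frame_interval) || p$frame_interval <= 0)
    stop("frame_interval must be a positive number")
  if (length(p$train_onsets) != length(p$train_n_aps))
    stop("train_onsets and train_n_aps must have equal length")
  if (!is.finite(p$train_freq) || p$train_freq <= 0)
    stop("train_freq must be positive")
  w <- train_windows(p)
  if (nrow(w) > 0) {
    o <- order(w[, 1])
    w <- w[o, , drop = FALSE]
    if (any(w[, 1] < 0) || any(w[, 2] > p$total_duration))
      stop("train window outside total_duration")
    if (nrow(w) > 1 && any(w[-1, 1] < w[-nrow(w), 2]))
      stop("train windows overlap")
  }
  if (is.finite(p$baf_time)) {
    if (length(p$train_onsets) >= 2 && p$baf_time > sort(p$train_onsets)[2])
      stop("baf_time must precede the second train onset")
  }
  last_off <- if (nrow(w) > 0) max(w[, 2]) else 0
  for (nm in c("nh4cl_time", "ionomycin_time")) {
    t <- p[[nm]]
    if (is.finite(t)) {
      if (t < last_off) stop(nm, " must follow all trains")
      if (t > p$total_duration) stop(nm, " beyond total_duration")
    }
  }
  invisible(p)
}

# 0/1 stimulation indicator evaluated at times tt
stim_indicator <- function(protocol, tt) {
  w <- train_windows(protocol)
  s <- numeric(length(tt))
  for (i in seq_len(nrow(w))) s[tt >= w[i, 1] & tt < w[i, 2]] <- 1
  s
}
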