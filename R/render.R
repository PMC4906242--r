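#' Rendering parameters for simulated movies
#'
#' Boutons are rendered as 2-D Gaussian spots (integrated intensity
#' normalized to 1) whose brightness follows
#' `amplitude * fluorescent_fraction(t)` on a constant background.  Noise is
#' the standard CCD model: Poisson shot noise on gain-scaled counts plus
#' additive Gaussian read noise.  Stage drift is applied as whole-frame
#' integer shifts; baseline drift as a slow additive ramp on a subset of
#' boutons.
#'
#' @param image_size integer `(H, W)` in pixels.
#' @param psf_sigma Gaussian spot width (pixels).
#' @param expression_mean median per-bouton amplitude (integrated counts at
#'   fluorescent fraction 1).
#' @param expression_lognorm_sigma lognormal spread of amplitudes.
#' @param background_level background counts per pixel.
#' @param gain camera gain for the Poisson branch (counts per photon);
#'   `0` disables shot noise.
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @param stage_drift data.frame with columns `frame`, `dx`, `dy` (integer
#'   shifts applied from that frame on), or `NULL`.
#' @param baseline_drift_slope counts/s ramp applied to drifting boutons.
#' @param drift_frac fraction of boutons receiving the baseline ramp.
#' @param min_dist minimum bouton center-to-center distance (pixels).
#' @return An object of class `svc_render`.
#' @export
render_params <- function(image_size = c(256, 256), psf_sigma = 1.5,
                          expression_mean = 10000,
                          expression_lognorm_sigma = 0.4,
                          background_level = 50, gain = 1,
                          read_noise_sd = 3, stage_drift = NULL,
                          baseline_drift_slope = 0, drift_frac = 0,
                          min_dist = 6) {
  stopifnot(length(image_size) == 2, all(image_size >= 16))
  structure(list(image_size = as.integer(image_size), psf_sigma = psf_sigma,
                 expression_mean = expression_mean,
                 expression_lognorm_sigma = expression_lognorm_sigma,
                 background_level = background_level, gain = gain,
                 read_noise_sd = read_noise_sd, stage_drift = stage_drift,
                 baseline_drift_slope = baseline_drift_slope,
                 drift_frac = drift_frac, min_dist = min_dist),
            class = "svc_render")
}

# Rejection-sample bouton centers with a minimum pairwise distance and an
# edge margin of 3 * psf_sigma.  Errors if the density is infeasible.
sample_positions <- function(n, render, max_tries = 200L) {
  H <- render$image_size[1]; W <- render$image_size[2]
  m <- ceiling(3 * render$psf_sigma)
  rows <- numeric(0); cols <- numeric(0)
  for (b in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      r <- stats::runif(1, m + 1, H - m)
      cl <- stats::runif(1, m + 1, W - m)
      if (length(rows) == 0 ||
          min((rows - r)^2 + (cols - cl)^2) >= render$min_dist^2) {
        rows <- c(rows, r); cols <- c(cols, cl); placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " boutons with min_dist = ",
           render$min_dist, " in a ", H, "x", W, " image")
  }
  cbind(row = rows, col = cols)
}

# Integer whole-frame shift with constant fill (frame median by default).
shift_frame <- function(frame, dy, dx, fill = stats::median(frame)) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render a movie from per-bouton fluorescence time courses
#'
#' @param fb matrix `[n_boutons, n_frames]` of per-bouton fluorescent
#'   fractions (or sensor traces), e.g. from [simulate_pools_multi] results.
#' @param render an [render_params()] object.
#' @param protocol an [stim_protocol()] (for frame times, used by baseline
#'   drift).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param positions optional matrix `(row, col)` of bouton centers; drawn
#'   if `NULL`.
#' @param quantize round and clamp to the 16-bit integer range (default);
#'   `FALSE` returns the continuous-valued frames (useful for exactness
#'   checks).
#' @return A list with `movie` (`[H, W, T]` array of 16-bit counts),
#'   `truth` (data.frame: positions, amplitude, drifter flag), and the
#'   applied `stage_drift`.
#' @export
render_movie <- function(fb, render, protocol, seed = 1L, positions = NULL,
                         quantize = TRUE) {
  set.seed(seed)
  nb <- nrow(fb); nf <- ncol(fb)
  H <- render$image_size[1]; W <- render$image_size[2]
  if (is.null(positions)) positions <- sample_positions(nb, render)
  amp <- stats::rlnorm(nb, log(render$expression_mean),
                       render$expression_lognorm_sigma)
  drifter <- stats::runif(nb) < render$drift_frac
  ft <- frame_times(protocol)[seq_len(nf)]

  # Gaussian patch per bouton, truncated at +-4 sigma, normalized to sum 1
  rad <- ceiling(4 * render$psf_sigma)
  scene <- array(render$background_level, c(H, W, nf))
  for (b in seq_len(nb)) {
    r0 <- round(positions[b, 1]); c0 <- round(positions[b, 2])
    rr <- max(1, r0 - rad):min(H, r0 + rad)
    cc <- max(1, c0 - rad):min(W, c0 + rad)
    gr <- exp(-(rr - positions[b, 1])^2 / (2 * render$psf_sigma^2))
    gc <- exp(-(cc - positions[b, 2])^2 / (2 * render$psf_sigma^2))
    patch <- outer(gr, gc)
    patch <- patch / sum(patch)
    tc <- amp[b] * fb[b, ]
    if (drifter[b] && render$baseline_drift_slope != 0)
      tc <- tc + render$baseline_drift_slope * ft
    scene[rr, cc, ] <- scene[rr, cc, ] +
      array(as.vector(patch) %o% tc, c(length(rr), length(cc), nf))
  }

  # stage drift: cumulative integer shifts from the listed frame onward
  if (!is.null(render$stage_drift) && nrow(render$stage_drift) > 0) {
    sd_tab <- render$stage_drift
    dx <- integer(nf); dy <- integer(nf)
    for (i in seq_len(nrow(sd_tab))) {
      from <- sd_tab$frame[i]
      dx[from:nf] <- dx[from:nf] + sd_tab$dx[i]
      dy[from:nf] <- dy[from:nf] + sd_tab$dy[i]
    }
    for (t in seq_len(nf))
      if (dx[t] != 0 || dy[t] != 0)
        scene[, , t] <- shift_frame(scene[, , t], dy[t], dx[t],
                                    fill = render$background_level)
    drift_applied <- data.frame(frame = seq_len(nf), dx = dx, dy = dy)
  } else {
    drift_applied <- data.frame(frame = seq_len(nf), dx = 0L, dy = 0L)
  }

  movie <- scene
  if (render$gain > 0) {
    movie[] <- render$gain *
      stats::rpois(length(scene), as.vector(scene) / render$gain)
  }
  if (render$read_noise_sd > 0)
    movie <- movie + stats::rnorm(length(movie), 0, render$read_noise_sd)
  if (quantize) {
    movie <- round(movie)
    movie[movie < 0] <- 0
    movie[movie > 65535] <- 65535
  }

  truth <- data.frame(bouton = seq_len(nb),
                      row = positions[, 1], col = positions[, 2],
                      amplitude = amp, drifter = drifter)
  list(movie = movie, truth = truth, stage_drift = drift_applied)
}

#' Simulate a full movie-level experiment
#'
#' Draws the hierarchical design, simulates per-bouton pool dynamics, and
#' renders one TIFF movie per field, writing a manifest and ground-truth
#' tables linking files to preparations, fields and groups.
#'
#' @param design an [hierarchy_design()].
#' @param kinetics an [kinetic_params()].
#' @param render an [render_params()].
#' @param protocol an [stim_protocol()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data.frame: file, prep_id,
#'   field_id, group) and `truth` (per-bouton ground truth incl. positions
#'   and amplitudes).  Files written: one TIFF per field, `manifest.csv`,
#'   `ground_truth.csv`, `params.json`.
#' @export
simulate_experiment <- function(design, kinetics, render, protocol,
                                dir = tempfile("svc_sim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- draw_hierarchy(design, kinetics)
  fields <- unique(truth$field_id)
  man <- vector("list", length(fields))
  truth$row <- NA_real_; truth$col <- NA_real_
  truth$amplitude <- NA_real_; truth$drifter <- NA
  for (i in seq_along(fields)) {
    fid <- fields[i]
    sel <- truth$field_id == fid
    sub <- truth[sel, ]
    pools <- simulate_pools_multi(sub$k_exo, sub$k_endo, kinetics, protocol)
    rm_seed <- design$seed + i    # per-field reproducible stream
    rend <- render_movie(pools$f, render, protocol, seed = rm_seed)
    file <- file.path(dir, paste0(fid, ".tif"))
    write_tiff(rend$movie, file)
    truth$row[sel] <- rend$truth$row
    truth$col[sel] <- rend$truth$col
    truth$amplitude[sel] <- rend$truth$amplitude
    truth$drifter[sel] <- rend$truth$drifter
    man[[i]] <- data.frame(file = basename(file),
                           prep_id = sub$prep_id[1], field_id = fid,
                           group = sub$group[1], seed = rm_seed,
                           stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(design = unclass(design), kinetics = unclass(kinetics),
         render = unclass(render[setdiff(names(render), "stage_drift")]),
         protocol = unclass(protocol)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  invisible(list(dir = dir, manifest = manifest, truth = truth))
}
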