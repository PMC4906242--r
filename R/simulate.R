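#' Kinetic parameters of the simulated synaptic vesicle cycle
#'
#' First-order pool-transfer model.  During an AP train, exocytosis drains
#' the remaining releasable pool at rate `k_exo`; endocytosis retrieves the
#' surface pool at rate `k_endo` at all times; internalized reporter
#' re-acidifies (and re-joins the releasable pool) with time constant
#' `tau_reacid`, which Baf sets to infinity.  Quenched reporter still emits
#' `quench_ratio` of the unquenched brightness (~20-fold unquenching).
#'
#' Defaults are chosen so that, under the standard two-train protocol, the
#' fitted exocytic rate is roughly three times the endocytic rate, the regime
#' reported for hippocampal boutons; absolute rate constants are simulator
#' constructs, not measured values.
#'
#' @param k_exo per-second exocytosis rate constant (releasable pool).
#' @param k_endo per-second endocytosis rate constant (surface pool).
#' @param tau_reacid re-acidification time constant (s); `Inf` disables.
#' @param releasable_fraction fraction of total reporter that is releasable.
#' @param quench_ratio brightness of quenched relative to unquenched reporter.
#' @param tau_repool maturation time constant (s) with which re-acidified
#'   vesicles become release-competent again; slow relative to a train, fast
#'   relative to the inter-train recovery interval.
#' @return An object of class `svc_kinetics`.
#' @export
kinetic_params <- function(k_exo = 0.025, k_endo = 0.028, tau_reacid = 4,
                           releasable_fraction = 0.3, quench_ratio = 1 / 20,
                           tau_repool = 60) {
  for (v in c(k_exo, k_endo, tau_reacid, releasable_fraction, quench_ratio,
              tau_repool))
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("kinetic parameters must be finite scalars (taus may be Inf)")
  if (k_exo < 0 || k_endo < 0 || tau_reacid <= 0 || tau_repool <= 0)
    stop("rates must be >= 0 and time constants > 0")
  if (!is.finite(k_exo) || !is.finite(k_endo))
    stop("k_exo and k_endo must be finite")
  if (releasable_fraction <= 0 || releasable_fraction > 1)
    stop("releasable_fraction must be in (0, 1]")
  if (quench_ratio <= 0 || quench_ratio >= 1)
    stop("quench_ratio must be in (0, 1)")
  structure(list(k_exo = k_exo, k_endo = k_endo, tau_reacid = tau_reacid,
                 releasable_fraction = releasable_fraction,
                 quench_ratio = quench_ratio, tau_repool = tau_repool),
            class = "svc_kinetics")
}

#' Vectorized pool simulation across boutons
#'
#' Forward Euler as in [simulate_pools()], but for a vector of per-bouton
#' rate constants sharing one protocol (the workhorse behind field-level
#' simulation).
#'
#' @param k_exo,k_endo numeric vectors of per-bouton rate constants.
#' @param kinetics an [kinetic_params()] supplying the shared parameters.
#' @param protocol an [stim_protocol()].
#' @param dt integration step (s); capped at `frame_interval / 10`.
#' @return List of matrices `[n_boutons x n_frames]`: `q`, `s`, `i`, `f`,
#'   `exo`, `endo`, `reacid`, plus `time`.
#' @export
simulate_pools_multi <- function(k_exo, k_endo, kinetics, protocol,
                                 dt = NULL) {
  validate_protocol(protocol)
  if (is.null(dt)) dt <- protocol$frame_interval / 10
  if (dt > protocol$frame_interval / 10) dt <- protocol$frame_interval / 10
  nb <- length(k_exo)
  stopifnot(length(k_endo) == nb)
  if (any(!is.finite(k_exo)) || any(!is.finite(k_endo)) ||
      any(k_exo < 0) || any(k_endo < 0))
    stop("rate constants must be finite and non-negative")

  rf <- kinetics$releasable_fraction
  qr <- kinetics$quench_ratio
  tau <- kinetics$tau_reacid
  ft <- frame_times(protocol)
  nf <- length(ft)

  tau_rp <- kinetics$tau_repool
  # state per bouton: R releasable (quenched), s surface, i internalized
  # (fluorescent), P re-acidified awaiting repooling (quenched)
  R <- rep(rf, nb); s <- numeric(nb); i <- numeric(nb); P <- numeric(nb)
  exo_c <- numeric(nb); endo_c <- numeric(nb); reac_c <- numeric(nb)

  out_names <- c("q", "s", "i", "f", "exo", "endo", "reacid")
  out <- lapply(out_names, function(x) matrix(0, nb, nf))
  names(out) <- out_names

  record <- function(j) {
    q_tot <- R + P + (1 - rf)             # quenched: releasable + recycled + reserve
    f <- if (is.finite(protocol$nh4cl_time) && ft[j] >= protocol$nh4cl_time)
      rep(1, nb) else s + i + qr * q_tot
    out$q[, j] <<- q_tot
    out$s[, j] <<- s
    out$i[, j] <<- i
    out$f[, j] <<- f
    out$exo[, j] <<- exo_c
    out$endo[, j] <<- endo_c
    out$reacid[, j] <<- reac_c
  }

  record(1)
  t <- 0
  for (j in 2:nf) {
    nstep <- max(1L, round((ft[j] - ft[j - 1]) / dt))
    h <- (ft[j] - ft[j - 1]) / nstep
    for (k in seq_len(nstep)) {
      stim <- stim_indicator(protocol, t)
      baf <- is.finite(protocol$baf_time) && t >= protocol$baf_time
      j_exo <- if (stim > 0) k_exo * R else rep(0, nb)
      j_endo <- k_endo * s
      j_reac <- if (baf || !is.finite(tau)) rep(0, nb) else i / tau
      j_pool <- if (is.finite(tau_rp)) P / tau_rp else rep(0, nb)
      R <- R - h * j_exo + h * j_pool
      s <- s + h * j_exo - h * j_endo
      i <- i + h * j_endo - h * j_reac
      P <- P + h * j_reac - h * j_pool
      exo_c <- exo_c + h * j_exo
      endo_c <- endo_c + h * j_endo
      reac_c <- reac_c + h * j_reac
      t <- t + h
    }
    record(j)
  }
  out$time <- ft
  out
}

#' Simulate synaptic vesicle pool dynamics
#'
#' Forward-simulates the pool-transfer model for one parameter set under a
#' stimulation protocol, returning per-frame pool fractions, the fluorescent
#' fraction, and cumulative exo-/endocytosis.  Integration is forward Euler
#' at a step no larger than one tenth of the frame interval.
#'
#' The fluorescent fraction is `f(t) = s(t) + i(t) + quench_ratio * q(t)`
#' (surface + internalized-not-yet-reacidified + residual brightness of the
#' quenched pool) and jumps to 1 after NH4Cl, which unquenches everything.
#' With Baf active, internalized reporter never re-acidifies.
#'
#' @param kinetics an [kinetic_params()] object.
#' @param protocol an [stim_protocol()] object.
#' @param dt integration step (s); capped at `frame_interval / 10`.
#' @return A data.frame with columns `time`, `q`, `s`, `i`, `f`, `exo`,
#'   `endo`, `reacid` evaluated at frame times.
#' @examples
#' pools <- simulate_pools(kinetic_params(), stim_protocol())
#' max(pools$exo)
#' @export
simulate_pools <- function(kinetics, protocol, dt = NULL) {
  stopifnot(inherits(kinetics, "svc_kinetics"))
  r <- simulate_pools_multi(kinetics$k_exo, kinetics$k_endo, kinetics,
                            protocol, dt = dt)
  data.frame(time = r$time, q = r$q[1, ], s = r$s[1, ], i = r$i[1, ],
             f = r$f[1, ], exo = r$exo[1, ], endo = r$endo[1, ],
             reacid = r$reacid[1, ])
}

#' Calcium sensor parameters
#'
#' Minimal presynaptic Ca2+ model for a vesicle-targeted GCaMP-type sensor:
#' free concentration rises at `influx_rate * group_scale` during
#' stimulation, relaxes back to the resting level with time constant
#' `tau_clear`, and is read out through a Hill saturation with
#' half-saturation `kd` and coefficient `hill`.  Ionomycin saturates the
#' sensor, providing the normalization maximum.
#'
#' Concentration is in units of `kd` by default; only the normalized
#' fluorescence is meaningful downstream.
#'
#' @param influx_rate concentration units per second during stimulation.
#' @param tau_clear clearance time constant (s).
#' @param kd half-saturation constant (concentration units).
#' @param hill Hill coefficient (> 0).
#' @param c_rest resting free concentration.
#' @param group_scale multiplicative factor on `influx_rate` (group effect).
#' @return An object of class `svc_ca`.
#' @export
ca_params <- function(influx_rate = 0.5, tau_clear = 2, kd = 1, hill = 2,
                      c_rest = 0.2, group_scale = 1) {
  if (!is.numeric(hill) || hill <= 0) stop("hill must be > 0")
  vals <- c(influx_rate, tau_clear, kd, c_rest, group_scale)
  if (any(!is.finite(vals)) || any(vals < 0) || tau_clear == 0 || kd == 0)
    stop("calcium parameters must be finite and positive")
  structure(list(influx_rate = influx_rate, tau_clear = tau_clear, kd = kd,
                 hill = hill, c_rest = c_rest, group_scale = group_scale),
            class = "svc_ca")
}

#' Simulate a presynaptic calcium sensor trace
#'
#' @param ca a [ca_params()] object.
#' @param protocol an [stim_protocol()] with `ionomycin_time` set.
#' @param dt integration step (s); capped at `frame_interval / 10`.
#' @return A data.frame with `time`, free concentration `conc`, and sensor
#'   fluorescence `f` (Hill occupancy, 1 after ionomycin).
#' @export
simulate_ca_trace <- function(ca, protocol, dt = NULL) {
  stopifnot(inherits(ca, "svc_ca"))
  validate_protocol(protocol)
  if (!is.finite(protocol$ionomycin_time))
    stop("protocol must include ionomycin_time for calcium simulation")
  if (is.null(dt)) dt <- protocol$frame_interval / 10
  if (dt > protocol$frame_interval / 10) dt <- protocol$frame_interval / 10
  ft <- frame_times(protocol)
  nf <- length(ft)
  conc <- numeric(nf)
  occ <- function(c) c^ca$hill / (c^ca$hill + ca$kd^ca$hill)
  cc <- ca$c_rest
  conc[1] <- cc
  t <- 0
  for (j in 2:nf) {
    nstep <- max(1L, round((ft[j] - ft[j - 1]) / dt))
    h <- (ft[j] - ft[j - 1]) / nstep
    for (k in seq_len(nstep)) {
      stim <- stim_indicator(protocol, t)
      cc <- cc + h * (ca$influx_rate * ca$group_scale * stim -
                        (cc - ca$c_rest) / ca$tau_clear)
      t <- t + h
    }
    conc[j] <- cc
  }
  f <- occ(conc)
  f[ft >= protocol$ionomycin_time] <- 1
  data.frame(time = ft, conc = conc, f = f)
}

#' Hierarchical experimental design
#'
#' Describes the nesting of the simulated experiment: preparations (neuron
#' cultures) contain imaged fields, fields contain boutons.  Field- and
#' bouton-level lognormal multipliers perturb the kinetic rate constants,
#' creating the intra-field correlation that the clustered statistics must
#' account for.  Each field carries one group label; group effects multiply
#' `k_exo`.
#'
#' Defaults mirror the scale of a typical dataset: 6 preparations with 3
#' fields each (18 fields per condition) and ~55 boutons per field, i.e.
#' about a thousand boutons per condition.
#'
#' @param n_preps number of preparations.
#' @param fields_per_prep fields imaged per preparation (per group).
#' @param boutons_per_field boutons per field.
#' @param sigma_field SD of the lognormal field-level rate multiplier.
#' @param sigma_bouton SD of the lognormal bouton-level rate multiplier.
#' @param group_effects named numeric vector, multiplier on `k_exo` per
#'   group; names are the group labels (first is taken as control).
#' @param seed integer seed; identical seed and design give identical output.
#' @return An object of class `svc_design`.
#' @export
hierarchy_design <- function(n_preps = 6, fields_per_prep = 3,
                             boutons_per_field = 55,
                             sigma_field = 0.25, sigma_bouton = 0.2,
                             group_effects = c(ctrl = 1.0), seed = 1L) {
  if (sigma_field < 0 || sigma_bouton < 0) stop("sigma values must be >= 0")
  if (is.null(names(group_effects)) || any(!nzchar(names(group_effects))))
    stop("group_effects must be a named vector")
  if (anyDuplicated(names(group_effects)))
    stop("duplicate group labels")
  structure(list(n_preps = as.integer(n_preps),
                 fields_per_prep = as.integer(fields_per_prep),
                 boutons_per_field = as.integer(boutons_per_field),
                 sigma_field = sigma_field, sigma_bouton = sigma_bouton,
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "svc_design")
}

#' Draw the hierarchical ground truth
#'
#' One row per bouton with true rate constants and provenance.  Every group
#' is imaged in every preparation (`fields_per_prep` fields per group per
#' prep); field- and bouton-level lognormal multipliers (mean 1) scale both
#' rate constants, and the group effect scales `k_exo`.
#'
#' @param design an [hierarchy_design()].
#' @param kinetics an [kinetic_params()].
#' @return data.frame: `prep_id`, `field_id`, `group`, `bouton_id`,
#'   `k_exo`, `k_endo`, `field_mult`, `bouton_mult`.
#' @export
draw_hierarchy <- function(design, kinetics) {
  set.seed(design$seed)
  groups <- names(design$group_effects)
  rows <- list()
  fid <- 0L
  for (p in seq_len(design$n_preps)) {
    for (g in groups) {
      for (fl in seq_len(design$fields_per_prep)) {
        fid <- fid + 1L
        mult_f <- stats::rlnorm(1, -design$sigma_field^2 / 2,
                                design$sigma_field)
        nb <- design$boutons_per_field
        mult_b <- stats::rlnorm(nb, -design$sigma_bouton^2 / 2,
                                design$sigma_bouton)
        rows[[fid]] <- data.frame(
          prep_id = sprintf("prep%02d", p),
          field_id = sprintf("field%03d", fid),
          group = g,
          bouton_id = sprintf("f%03d_b%03d", fid, seq_len(nb)),
          k_exo = kinetics$k_exo * design$group_effects[[g]] * mult_f * mult_b,
          k_endo = kinetics$k_endo * mult_f * mult_b,
          field_mult = mult_f,
          bouton_mult = mult_b,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  if (anyDuplicated(vapply(rows, function(r) r$field_id[1], character(1))))
    stop("duplicate field ids")
  truth
}

#' Simulate a hierarchical trace-level experiment
#'
#' Fast route that skips movie rendering: draws the hierarchy, simulates
#' per-bouton pool dynamics, and returns normalized traces with additive
#' Gaussian measurement noise (the noise level a bouton trace shows after
#' NH4Cl normalization of a rendered movie).  Optionally plants baseline
#' drift in a fraction of boutons so the QC filter can be exercised.
#'
#' @param design an [hierarchy_design()].
#' @param kinetics an [kinetic_params()]; group/field/bouton multipliers act
#'   on its rate constants.
#' @param protocol an [stim_protocol()].
#' @param noise_sd per-frame Gaussian noise SD in normalized units.
#' @param drift_frac fraction of boutons receiving a baseline ramp.
#' @param drift_slope ramp slope (normalized units per second).
#' @return A list with `traces` (an `svc_traces` object, see
#'   [extract_traces()]) and `truth` (per-bouton data.frame including a
#'   `drifter` flag and noiseless pool curves in attribute `pools`).
#' @export
simulate_trace_experiment <- function(design, kinetics, protocol,
                                      noise_sd = 0.01, drift_frac = 0,
                                      drift_slope = 0) {
  truth <- draw_hierarchy(design, kinetics)
  nb <- nrow(truth)
  pools <- simulate_pools_multi(truth$k_exo, truth$k_endo, kinetics, protocol)
  ft <- pools$time
  nf <- length(ft)
  norm <- pools$f
  drifter <- rep(FALSE, nb)
  if (drift_frac > 0) {
    drifter <- stats::runif(nb) < drift_frac
    if (any(drifter)) {
      ramp <- outer(rep(drift_slope, sum(drifter)), ft)
      pre_nh4 <- if (is.finite(protocol$nh4cl_time))
        ft < protocol$nh4cl_time else rep(TRUE, nf)
      ramp[, !pre_nh4] <- 0   # NH4Cl saturation unaffected by drift
      norm[drifter, ] <- norm[drifter, , drop = FALSE] + ramp
    }
  }
  if (noise_sd > 0)
    norm <- norm + matrix(stats::rnorm(nb * nf, 0, noise_sd), nb, nf)
  truth$drifter <- drifter
  meta <- data.frame(bouton_id = truth$bouton_id, prep_id = truth$prep_id,
                     field_id = truth$field_id, group = truth$group,
                     qc_status = "kept", stringsAsFactors = FALSE)
  tr <- new_traces(time = ft, norm = norm, raw = norm, meta = meta,
                   f_ref = rep(1, nb))
  attr(truth, "pools") <- pools
  list(traces = tr, truth = truth)
}

#' Simulate clustered outcome tables
#'
#' Generates bouton-level outcomes with Gaussian random field effects for
#' calibrating the clustered statistics: `y = mu_g + u_field + e`, with
#' `u_field ~ N(0, sigma_f^2)` and `e ~ N(0, sigma^2)`, so the intraclass
#' correlation is `sigma_f^2 / (sigma_f^2 + sigma^2)`.
#'
#' @param group_means named numeric vector of group means.
#' @param fields_per_group fields per group.
#' @param boutons_per_field boutons per field.
#' @param icc intraclass correlation in `[0, 1)`; total variance is 1.
#' @param n_preps preparations (fields assigned round-robin).
#' @return An outcome data.frame with columns `y`, `field_id`, `prep_id`,
#'   `group`.
#' @export
simulate_outcome_table <- function(group_means = c(ctrl = 0, kd = 0),
                                   fields_per_group = 15,
                                   boutons_per_field = 10,
                                   icc = 0.2, n_preps = 3) {
  stopifnot(icc >= 0, icc < 1)
  sf <- sqrt(icc); se <- sqrt(1 - icc)
  groups <- names(group_means)
  rows <- vector("list", length(groups) * fields_per_group)
  fid <- 0L
  for (g in groups) {
    for (fl in seq_len(fields_per_group)) {
      fid <- fid + 1L
      u <- stats::rnorm(1, 0, sf)
      y <- group_means[[g]] + u +
        stats::rnorm(boutons_per_field, 0, se)
      rows[[fid]] <- data.frame(
        y = y,
        field_id = sprintf("field%03d", fid),
        prep_id = sprintf("prep%02d", ((fid - 1L) %% n_preps) + 1L),
        group = g, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
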