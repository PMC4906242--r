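#' Modified Boltzmann I-V model
#'
#' Current density as a driving-force times activation product:
#' `I(V) = Gmax * (Erev - V) / (1 + exp((V_half - V) / k))`.
#'
#' @param V test potentials (mV).
#' @param gmax maximum conductance (nS/pF).
#' @param erev reversal potential (mV).
#' @param v_half half-activation voltage (mV).
#' @param k slope factor (mV, > 0).
#' @return Current density (pA/pF) at each `V`.
#' @export
boltzmann_iv <- function(V, gmax, erev, v_half, k) {
  gmax * (erev - V) / (1 + exp((v_half - V) / k))
}

#' Single Boltzmann activation model
#'
#' `I(V) = I_min + (I_max - I_min) / (1 + exp((V_half - V) / k))`.
#' Used for tail-current activation curves; the printed parameter symbols
#' of the voltage-clamp protocol (`V1/2inact`, `k_inact`) are kept as
#' metadata aliases even though the tail protocol measures activation.
#'
#' @param V step potentials (mV).
#' @param i_min,i_max minimal and maximal current.
#' @param v_half half-maximal voltage (mV).
#' @param k slope factor (mV, > 0).
#' @return Current at each `V`.
#' @export
boltzmann_act <- function(V, i_min, i_max, v_half, k) {
  i_min + (i_max - i_min) / (1 + exp((v_half - V) / k))
}

# Shared NLS driver: port algorithm (trust-region with bounds), seeded
# multistart on non-convergence.
nls_multistart <- function(formula, data, start, lower, upper,
                           jitter = 0.2, tries = 3L, seed = 1L) {
  fit <- tryCatch(
    stats::nls(formula, data = data, start = start, lower = lower,
               upper = upper, algorithm = "port",
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  set.seed(seed)
  for (i in seq_len(tries)) {
    st <- lapply(start, function(v) v * (1 + stats::rnorm(1, 0, jitter)) +
                   stats::rnorm(1, 0, jitter))
    st <- Map(function(v, lo, hi) min(max(v, lo + 1e-6), hi - 1e-6),
              st, as.list(lower)[names(st)], as.list(upper)[names(st)])
    fit <- tryCatch(
      stats::nls(formula, data = data, start = st, lower = lower,
                 upper = upper, algorithm = "port",
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' Fit the modified Boltzmann to an I-V curve
#'
#' Initialization follows the geometry of the curve: `Erev` from the linear
#' zero crossing beyond the peak, `V_half` at half-maximal current,
#' `k = 5` mV, `Gmax` from the peak amplitude; `k` is bounded to
#' (0.1, 30) mV.  Currents are expected on the positive-density convention
#' (peak inward current positive); a predominantly negative curve is
#' sign-flipped at ingest with a message.
#'
#' @param V test potentials (mV), any order.
#' @param I current densities (pA/pF).
#' @return List of class `svc_iv_fit`: `gmax`, `erev`, `v_half`, `k`,
#'   `residual_norm`, `converged`, `fitted`, and the (possibly flipped)
#'   inputs.
#' @export
fit_iv <- function(V, I) {
  o <- order(V); V <- V[o]; I <- I[o]
  if (length(unique(V)) < 6) stop("need >= 6 distinct potentials")
  if (all(I == 0)) stop("all-zero currents")
  if (min(I) < 0 && abs(min(I)) > abs(max(I))) {
    message("negative-dominant currents: flipping sign to density convention")
    I <- -I
  }
  ipk <- which.max(I)
  # Erev init: linear zero crossing on the descending limb past the peak
  post <- seq(ipk, length(V))
  erev0 <- if (length(post) >= 2) {
    cs <- stats::coef(stats::lm(I[post] ~ V[post]))
    if (is.finite(cs[2]) && cs[2] < 0) -cs[1] / cs[2] else max(V) + 20
  } else max(V) + 20
  erev0 <- max(erev0, V[ipk] + 5)
  half <- I[ipk] / 2
  pre <- seq_len(ipk)
  vh0 <- V[pre][which.min(abs(I[pre] - half))]
  g0 <- I[ipk] / max(erev0 - V[ipk], 1)
  d <- data.frame(V = V, I = I)
  fit <- nls_multistart(
    I ~ gmax * (erev - V) / (1 + exp((v_half - V) / k)), d,
    start = list(gmax = g0, erev = erev0, v_half = vh0, k = 5),
    lower = c(gmax = 1e-8, erev = V[ipk], v_half = min(V) - 50, k = 0.1),
    upper = c(gmax = Inf, erev = max(V) + 200, v_half = max(V) + 50,
              k = 30))
  if (is.null(fit)) stop("I-V fit did not converge")
  cf <- stats::coef(fit)
  structure(list(gmax = unname(cf["gmax"]), erev = unname(cf["erev"]),
                 v_half = unname(cf["v_half"]), k = unname(cf["k"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, V = V, I = I,
                 fitted = stats::fitted(fit)),
            class = "svc_iv_fit")
}

#' Fit the single Boltzmann to tail-current activation data
#'
#' @param V step potentials (mV), any order.
#' @param I tail-current amplitudes.
#' @return List of class `svc_act_fit`: `i_min`, `i_max`, `v_half`, `k`,
#'   `residual_norm`, `converged`, `fitted`, `activation` (normalized curve
#'   `(I - I_min)/(I_max - I_min)` at the input potentials), and printed-
#'   symbol aliases in `$aliases`.
#' @export
fit_activation <- function(V, I) {
  o <- order(V); V <- V[o]; I <- I[o]
  if (length(unique(V)) < 6) stop("need >= 6 distinct potentials")
  rng <- max(I) - min(I)
  if (rng <= max(1e-12, 10 * .Machine$double.eps * max(abs(I), 1)))
    stop("flat input: no activation range above noise floor")
  half <- min(I) + rng / 2
  vh0 <- V[which.min(abs(I - half))]
  d <- data.frame(V = V, I = I)
  fit <- nls_multistart(
    I ~ i_min + (i_max - i_min) / (1 + exp((v_half - V) / k)), d,
    start = list(i_min = min(I), i_max = max(I), v_half = vh0, k = 5),
    lower = c(i_min = -Inf, i_max = -Inf, v_half = min(V) - 100, k = 0.1),
    upper = c(i_min = Inf, i_max = Inf, v_half = max(V) + 100, k = 30))
  if (is.null(fit)) stop("activation fit did not converge")
  cf <- stats::coef(fit)
  act <- (I - cf["i_min"]) / (cf["i_max"] - cf["i_min"])
  structure(list(i_min = unname(cf["i_min"]), i_max = unname(cf["i_max"]),
                 v_half = unname(cf["v_half"]), k = unname(cf["k"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, V = V, I = I,
                 fitted = stats::fitted(fit), activation = unname(act),
                 aliases = c(V1_2inact = unname(cf["v_half"]),
                             k_inact = unname(cf["k"]))),
            class = "svc_act_fit")
}

#' Simulate voltage-clamp sweeps
#'
#' Model-exact at zero noise; multiplicative Gaussian noise otherwise.
#'
#' @param params named list of model parameters (`gmax`, `erev`, `v_half`,
#'   `k` for `model = "iv"`; `i_min`, `i_max`, `v_half`, `k` for
#'   `model = "activation"`).
#' @param grid potentials (mV); defaults: -50..40 (I-V), -60..60 (tail),
#'   10 mV steps.
#' @param noise multiplicative noise SD (fraction of each value).
#' @param model `"iv"` or `"activation"`.
#' @param seed RNG seed for the noise draw.
#' @return data.frame with `V` and `I`.
#' @export
simulate_sweeps <- function(params, grid = NULL, noise = 0,
                            model = c("iv", "activation"), seed = 1L) {
  model <- match.arg(model)
  if (is.null(grid)) grid <- if (model == "iv") seq(-50, 40, 10) else
    seq(-60, 60, 10)
  if (length(grid) == 0) stop("empty potential grid")
  I <- if (model == "iv")
    boltzmann_iv(grid, params$gmax, params$erev, params$v_half, params$k)
  else
    boltzmann_act(grid, params$i_min, params$i_max, params$v_half, params$k)
  if (noise > 0) {
    set.seed(seed)
    I <- I * (1 + stats::rnorm(length(I), 0, noise))
  }
  data.frame(V = grid, I = I)
}

#' Compare peak current densities between two groups of cells
#'
#' Reports group means with SEM, the percent change of group B relative to
#' group A (`100 * (mean_B - mean_A) / mean_A`), and a Welch two-sample
#' test on the per-cell values.
#'
#' @param a,b numeric vectors of per-cell peak densities (pA/pF).
#' @param labels group labels (length 2).
#' @return List of class `svc_group_cmp` with `means`, `sems`, `n`,
#'   `percent_change`, `t`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b, labels = c("A", "B")) {
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 cells per group")
  tt <- stats::t.test(b, a)   # Welch
  ma <- mean(a); mb <- mean(b)
  structure(list(
    means = stats::setNames(c(ma, mb), labels),
    sems = stats::setNames(c(stats::sd(a) / sqrt(length(a)),
                             stats::sd(b) / sqrt(length(b))), labels),
    n = stats::setNames(c(length(a), length(b)), labels),
    percent_change = 100 * (mb - ma) / ma,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value), class = "svc_group_cmp")
}

#' Welch test from summary statistics
#'
#' Closed-form Welch t-test when only group means, SEMs and sizes are
#' available (e.g. values printed in a figure caption).
#'
#' @param m1,m2 group means.
#' @param sem1,sem2 standard errors of the means.
#' @param n1,n2 group sizes.
#' @return List with `t`, `df` (Welch-Satterthwaite), `p_value`, and
#'   `percent_change` of group 2 vs group 1.
#' @export
welch_from_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  se2 <- sem1^2 + sem2^2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       percent_change = 100 * (m2 - m1) / m1)
}
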