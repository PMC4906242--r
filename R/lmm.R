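# Outcome tables are plain data.frames with columns: y (or another outcome
# column), field_id, prep_id, group. Boutons are rows; each field belongs to
# exactly one prep and one group.

check_outcome_table <- function(data, outcome = "y") {
  need <- c(outcome, "field_id", "group")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("outcome table lacks columns: ",
                         paste(miss, collapse = ", "))
  f2g <- tapply(data$group, data$field_id, function(g) length(unique(g)))
  if (any(f2g > 1)) stop("a field maps to more than one group")
  if ("prep_id" %in% names(data)) {
    f2p <- tapply(data$prep_id, data$field_id,
                  function(p) length(unique(p)))
    if (any(f2p > 1)) stop("a field maps to more than one prep")
  }
  invisible(data)
}

#' Fit the clustered linear mixed model
#'
#' Bouton-level outcomes are modeled as
#' `y = mu_group + pi_prep + u_field + e`, with normally distributed random
#' field effects `u_field ~ N(0, sigma_f^2)` and residuals `e ~ N(0,
#' sigma^2)`; preparations enter as fixed effects (sum-to-zero coded, so the
#' group coefficients are means at the average preparation).  Estimation is
#' restricted maximum likelihood with the variance ratio
#' `theta = sigma_f^2 / sigma^2` profiled out in one dimension; fixed
#' effects are the GLS solution at the optimum.  A negative variance
#' estimate is truncated at zero and flagged.
#'
#' @param data outcome table (see above).
#' @param outcome outcome column name.
#' @param use_prep include preparation fixed effects (dropped with a warning
#'   when confounded with group or absent).
#' @param theta_fixed evaluate at a pinned variance ratio instead of
#'   optimizing (diagnostics / profiling).
#' @return An object of class `svc_lmm`: `beta`, `vcov`, `sigma2`,
#'   `sigma_f2`, `icc`, `group_means`, `criterion` (-2 REML log-likelihood
#'   up to a constant), `boundary`, `converged`.
#' @export
fit_lmm <- function(data, outcome = "y", use_prep = TRUE,
                    theta_fixed = NULL) {
  check_outcome_table(data, outcome)
  y <- data[[outcome]]
  if (any(!is.finite(y))) stop("non-finite outcome values")
  group <- factor(data$group)
  field <- factor(data$field_id)
  G <- nlevels(group)
  if (any(table(unique(data.frame(group, field))$group) < 2))
    stop("need >= 2 fields per group")
  Xg <- vapply(levels(group), function(l) as.numeric(group == l),
               numeric(length(y)))
  colnames(Xg) <- levels(group)
  X <- Xg
  prep_used <- FALSE
  if (use_prep && "prep_id" %in% names(data) &&
      length(unique(data$prep_id)) > 1) {
    prep <- factor(data$prep_id)
    Xp <- stats::model.matrix(~ prep,
                              contrasts.arg = list(prep = "contr.sum"))[, -1,
                                                                        drop = FALSE]
    colnames(Xp) <- paste0("prep", seq_len(ncol(Xp)))
    Xfull <- cbind(Xg, Xp)
    if (qr(Xfull)$rank == ncol(Xfull)) {
      X <- Xfull
      prep_used <- TRUE
    } else {
      warning("preparation confounded with group; dropping prep term")
    }
  }
  n <- length(y); p <- ncol(X)
  fidx <- as.integer(field)
  nf_per <- tabulate(fidx)
  # per-field sufficient statistics
  Sx <- rowsum(X, fidx)                      # [F x p] field sums of X
  Sy <- rowsum(y, fidx)[, 1]                 # field sums of y
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y * y)

  crit <- function(theta) {
    w <- theta / (1 + nf_per * theta)        # shrinkage weight per field
    XtVX <- XtX - crossprod(Sx * w, Sx)
    XtVy <- Xty - colSums(Sx * (w * Sy))
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    rss <- yty - sum(w * Sy^2) - 2 * sum(beta * XtVy) +
      sum(beta * (XtVX %*% beta))
    # guard tiny negative from cancellation
    rss <- max(rss, 1e-300)
    sigma2 <- rss / (n - p)
    val <- (n - p) * log(sigma2) + sum(log1p(nf_per * theta)) +
      2 * sum(log(diag(ch)))
    list(val = val, beta = beta, sigma2 = sigma2, XtVX = XtVX)
  }

  if (is.null(theta_fixed)) {
    f <- function(lt) crit(exp(lt))$val
    opt <- stats::optimize(f, interval = c(-14, 10), tol = 1e-10)
    cands <- list(c(theta = exp(opt$minimum), val = opt$objective),
                  c(theta = 0, val = crit(0)$val))
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "val"))]]
    theta <- unname(best["theta"])
  } else {
    theta <- theta_fixed
  }
  boundary <- theta < 1e-10
  if (boundary) theta <- 0
  at <- crit(theta)
  beta <- at$beta
  names(beta) <- colnames(X)
  vcov <- at$sigma2 * solve(at$XtVX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  gm <- beta[levels(group)]
  structure(list(beta = beta, vcov = vcov, sigma2 = at$sigma2,
                 sigma_f2 = theta * at$sigma2,
                 icc = theta / (1 + theta),
                 theta = theta, group_means = gm,
                 groups = levels(group), n = n, p = p,
                 n_fields = nlevels(field), prep_used = prep_used,
                 criterion = at$val, boundary = boundary,
                 converged = TRUE, outcome = outcome),
            class = "svc_lmm")
}

#' @export
print.svc_lmm <- function(x, ...) {
  cat("Linear mixed model (REML), outcome:", x$outcome, "\n")
  cat(sprintf("  sigma_f^2 = %.4g, sigma^2 = %.4g, ICC = %.3f%s\n",
              x$sigma_f2, x$sigma2, x$icc,
              if (x$boundary) " [boundary]" else ""))
  cat("  group means:\n")
  print(round(x$group_means, 5))
  invisible(x)
}

new_test_result <- function(statistic, df, p, null, method) {
  structure(list(statistic = statistic, df = df, p_value = p,
                 null_hypothesis = null, method = method),
            class = "svc_test")
}

#' @export
print.svc_test <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, df = %s, p = %.4g\n  H0: %s\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value, x$null_hypothesis))
  invisible(x)
}

#' Wald test on mixed-model group means
#'
#' Two groups: z statistic on the difference of estimated group means with
#' its GLS standard error (normal reference by default; `df_method =
#' "between_within"` uses a fields-minus-parameters t reference as a
#' small-sample option).  More than two groups: joint chi-square Wald test
#' of all non-control groups against the control, `df = G - 1`.
#'
#' @param fit an `svc_lmm`.
#' @param control control group label (default: first group level).
#' @param groups groups to test against control (default: all others).
#' @param df_method `"z"` (default) or `"between_within"`.
#' @return An `svc_test`.
#' @export
wald_test <- function(fit, control = fit$groups[1], groups = NULL,
                      df_method = c("z", "between_within")) {
  df_method <- match.arg(df_method)
  if (!control %in% fit$groups) stop("unknown control group: ", control)
  if (is.null(groups)) groups <- setdiff(fit$groups, control)
  if (!all(groups %in% fit$groups)) stop("contrast references unknown group")
  if (length(groups) == 0 ||
      (length(groups) == 1 && groups == control)) {
    return(new_test_result(0, NA, 1, "group vs itself", "lmm_wald"))
  }
  C <- matrix(0, length(groups), length(fit$beta),
              dimnames = list(groups, names(fit$beta)))
  for (g in groups) { C[g, g] <- 1; C[g, control] <- -1 }
  est <- C %*% fit$beta
  V <- C %*% fit$vcov %*% t(C)
  if (length(groups) == 1) {
    z <- est[1] / sqrt(V[1, 1])
    if (df_method == "z") {
      p <- 2 * stats::pnorm(-abs(z)); df <- Inf
    } else {
      df <- max(1, fit$n_fields - fit$p)
      p <- 2 * stats::pt(-abs(z), df)
    }
    new_test_result(z, df, p,
                    sprintf("mean(%s) = mean(%s)", groups, control),
                    "lmm_wald")
  } else {
    W <- drop(t(est) %*% solve(V, est))
    df <- length(groups)
    p <- stats::pchisq(W, df, lower.tail = FALSE)
    new_test_result(W, df, p,
                    sprintf("all group means equal mean(%s)", control),
                    "lmm_wald")
  }
}

#' Field-heterogeneity test within a condition
#'
#' Treats field as a fixed factor within one condition and jointly tests
#' equality of field means (Wald, equivalently the one-way F test).  A
#' small p-value indicates strong intra-field correlation, i.e. boutons are
#' not independent observations.
#'
#' @param data outcome table.
#' @param outcome outcome column.
#' @param condition group label to subset to (default: use all rows,
#'   assumed one condition).
#' @return An `svc_test` with an F statistic and (df1, df2).
#' @export
heterogeneity_test <- function(data, outcome = "y", condition = NULL) {
  check_outcome_table(data, outcome)
  if (!is.null(condition)) data <- data[data$group == condition, ]
  y <- data[[outcome]]
  field <- factor(data$field_id)
  cnt <- table(field)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("dropping fields with < 2 boutons: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(field) %in% small)
    y <- y[keep]; field <- droplevels(field[keep])
  }
  k <- nlevels(field)
  if (k < 2) stop("need >= 2 fields in the condition")
  n <- length(y)
  gm <- mean(y)
  fm <- tapply(y, field, mean)
  nf <- tabulate(as.integer(field))
  ssb <- sum(nf * (fm - gm)^2)
  ssw <- sum((y - fm[as.integer(field)])^2)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  new_test_result(Fstat, c(k - 1, n - k), p,
                  "no difference in mean outcome across fields",
                  "heterogeneity_wald")
}

#' Field-averaging comparator
#'
#' Collapses each field to the mean of its bouton responses and compares
#' two groups with a pooled-variance two-sample t-test.  Valid under
#' clustering but statistically less efficient than the mixed model.
#'
#' @param data outcome table with exactly two groups.
#' @param outcome outcome column.
#' @return An `svc_test`.
#' @export
field_average_ttest <- function(data, outcome = "y") {
  check_outcome_table(data, outcome)
  g <- factor(data$group)
  if (nlevels(g) != 2) stop("field_average_ttest requires exactly 2 groups")
  fm <- tapply(data[[outcome]], data$field_id, mean)
  fg <- tapply(as.character(g), data$field_id, `[`, 1)
  sp <- split(fm, fg)
  if (any(lengths(sp) < 2)) stop("need >= 2 fields per group")
  tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = TRUE)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  "equal group means of field averages",
                  "field_avg_ttest")
}

#' Naive pooled bouton-level t-test (diagnostic only)
#'
#' Ignores clustering entirely; anticonservative whenever fields vary
#' (positive intraclass correlation).  Provided to demonstrate the
#' inflation, not for inference.
#'
#' @param data outcome table with exactly two groups.
#' @param outcome outcome column.
#' @return An `svc_test` (emits a warning about clustering).
#' @export
naive_pooled_ttest <- function(data, outcome = "y") {
  check_outcome_table(data, outcome)
  g <- factor(data$group)
  if (nlevels(g) != 2) stop("naive_pooled_ttest requires exactly 2 groups")
  sp <- split(data[[outcome]], g)
  if (any(lengths(sp) < 2)) stop("need >= 2 boutons per group")
  warning("naive pooled t-test ignores intra-field correlation; ",
          "anticonservative under clustering")
  tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = TRUE)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  "equal group means (boutons pooled)",
                  "naive_pooled_ttest")
}
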