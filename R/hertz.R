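#' Convert a force curve from photodetector volts to physical units
#'
#' deflection_m = deflection_V * sensitivity. Curves already in meters
#' are returned unchanged.
#'
#' @param curve a [force_curve()].
#' @return a [force_curve()] with deflection in meters.
#' @export
curve_to_physical <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  if (curve$units == "m") return(curve)
  sens <- curve$probe$deflection_sensitivity
  if (is.null(sens) || !is.finite(sens)) {
    stop("deflection in volts but probe has no deflection sensitivity")
  }
  force_curve(curve$z, curve$deflection * sens, curve$probe, units = "m",
              true_E = curve$true_E, true_contact = curve$true_contact)
}

# Piecewise two-regime residual at a candidate contact position z0:
# flat baseline (mean of pre-contact deflection) + through-origin Hertz rise
# F = a * delta^{3/2} with compliance-corrected delta = (z - z0) - d.
# Returns total RSS, or Inf if the split is unusable.
contact_split_rss <- function(z, d_m, k, z0, min_post = 5L) {
  pre <- z <= z0
  if (sum(pre) < 1L) return(list(rss = Inf))
  b <- mean(d_m[pre])
  dc <- d_m - b
  post <- !pre
  delta <- (z - z0) - dc
  use <- post & delta > 0
  if (sum(use) < min_post) return(list(rss = Inf))
  Fm <- k * dc[use]
  x <- delta[use]^1.5
  a <- sum(Fm * x) / sum(x^2)
  rss_post <- if (a > 0) sum((Fm - a * x)^2) else sum(Fm^2)
  rss <- sum((k * dc[pre])^2) + rss_post
  list(rss = rss, baseline = b, slope = a)
}

#' Detect the contact point of a force curve
#'
#' Two-regime piecewise fit: a flat pre-contact baseline and a
#' through-origin Hertz rise F = a * delta^{3/2} past the split. The
#' split is first located by exhaustive search over sample positions,
#' then refined continuously between the neighbouring samples by Brent
#' minimization of the same residual. On noiseless synthetic curves the
#' grid stage alone is within one sample spacing of the true contact;
#' the refinement recovers it to numerical precision.
#'
#' @param curve a [force_curve()] (volts are converted internally).
#' @param min_baseline minimum number of pre-contact samples (default 10).
#' @return list with `contact` (meters), `converged` (logical), and
#'   `grid_contact` (the unrefined sample-grid estimate). A curve with
#'   no detectable contact (e.g. all baseline) yields
#'   `converged = FALSE`, not an error.
#' @export
detect_contact_point <- function(curve, min_baseline = 10L) {
  curve <- curve_to_physical(curve)
  z <- curve$z; d_m <- curve$deflection
  if (z[1] > z[length(z)]) { z <- rev(z); d_m <- rev(d_m) }
  n <- length(z)
  k <- curve$probe$spring_constant
  if (n < min_baseline + 5L) {
    return(list(contact = NA_real_, converged = FALSE,
                grid_contact = NA_real_))
  }
  cand <- seq.int(min_baseline, n - 5L)
  rss <- rep(Inf, length(cand))
  slope <- rep(NA_real_, length(cand))
  for (j in seq_along(cand)) {
    r <- contact_split_rss(z, d_m, k, z[cand[j]])
    rss[j] <- r$rss
    slope[j] <- if (is.finite(r$rss)) r$slope else NA_real_
  }
  if (!any(is.finite(rss))) {
    return(list(contact = NA_real_, converged = FALSE,
                grid_contact = NA_real_))
  }
  jbest <- which.min(rss)
  if (!is.finite(slope[jbest]) || slope[jbest] <= 0) {
    return(list(contact = NA_real_, converged = FALSE,
                grid_contact = z[cand[jbest]]))
  }
  i <- cand[jbest]
  lo <- z[max(i - 1L, 1L)]; hi <- z[min(i + 1L, n)]
  obj <- function(z0) {
    r <- contact_split_rss(z, d_m, k, z0)
    if (!is.finite(r$rss)) 1e300 else r$rss
  }
  opt <- optimize(obj, interval = c(lo, hi), tol = 1e-13)
  list(contact = opt$minimum, converged = TRUE, grid_contact = z[i])
}

#' Fit the Hertz spherical-contact model to a force curve
#'
#' Linearized least-squares estimator: with baseline-corrected
#' deflection d, force F = k d and compliance-corrected indentation
#' delta = (z - z0) - d, the modulus follows from the through-origin
#' regression of F on delta^{3/2},
#' E = slope * (3/4) * (1 - nu^2) / sqrt(R). No iterative optimizer is
#' needed.
#'
#' @param curve a [force_curve()] (volts are converted internally).
#' @param contact contact point z0, meters (e.g. from
#'   [detect_contact_point()]).
#' @param max_depth optional cap on indentation depth used in the fit,
#'   meters (NULL = all post-contact points).
#' @return object of class `hertz_fit_result`: `youngs_modulus` (Pa),
#'   `contact_point`, `rms_residual` (N), `n_fit_points`, `converged`.
#' @export
fit_hertz <- function(curve, contact, max_depth = NULL) {
  curve <- curve_to_physical(curve)
  z <- curve$z; d_m <- curve$deflection
  if (z[1] > z[length(z)]) { z <- rev(z); d_m <- rev(d_m) }
  k <- curve$probe$spring_constant
  nu <- curve$probe$poisson_ratio
  R <- curve$probe$radius
  pre <- z <= contact
  b <- if (any(pre)) mean(d_m[pre]) else 0
  dc <- d_m - b
  delta <- (z - contact) - dc
  use <- (z > contact) & delta > 0
  if (!is.null(max_depth)) use <- use & delta <= max_depth
  res <- structure(list(youngs_modulus = NA_real_, contact_point = contact,
                        rms_residual = NA_real_,
                        n_fit_points = sum(use), converged = FALSE),
                   class = "hertz_fit_result")
  if (sum(use) < 5L) return(res)
  Fm <- k * dc[use]
  x <- delta[use]^1.5
  a <- sum(Fm * x) / sum(x^2)
  E <- a * (3 / 4) * (1 - nu^2) / sqrt(R)
  res$rms_residual <- sqrt(mean((Fm - a * x)^2))
  if (is.finite(E) && E > 0) {
    res$youngs_modulus <- E
    res$converged <- TRUE
  }
  res
}

#' Analyze one force curve end to end
#'
#' Contact detection followed by the linearized Hertz fit.
#'
#' @param curve a [force_curve()].
#' @param max_depth optional fit-depth cap, meters.
#' @return a `hertz_fit_result` (non-converged if no contact found).
#' @export
analyze_curve <- function(curve, max_depth = NULL) {
  det <- detect_contact_point(curve)
  if (!det$converged) {
    return(structure(list(youngs_modulus = NA_real_, contact_point = NA_real_,
                          rms_residual = NA_real_, n_fit_points = 0L,
                          converged = FALSE),
                     class = "hertz_fit_result"))
  }
  fit_hertz(curve, det$contact, max_depth = max_depth)
}

#' Summarize a group of Hertz fits
#'
#' Mean, sample SD and SEM = SD/sqrt(n) of the Young's modulus over the
#' converged fits; non-converged fits are counted and excluded. Both SD
#' and SEM are reported because a bare "+/-" in the literature is
#' ambiguous between them.
#'
#' @param results list of `hertz_fit_result` objects (or a numeric
#'   vector of moduli, Pa).
#' @param name group label carried into comparisons.
#' @return list of class `group_summary`: `name`, `n`, `n_excluded`,
#'   `mean_E`, `sd_E`, `sem_E` (SEM is NA for n = 1), and the raw
#'   per-cell moduli `E`.
#' @export
analyze_group <- function(results, name = "group") {
  if (is.numeric(results)) {
    E <- results
    n_exc <- 0L
  } else {
    conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
    E <- vapply(results[conv], function(r) r$youngs_modulus, numeric(1))
    n_exc <- sum(!conv)
  }
  if (length(E) == 0L) stop("no converged fits in group '", name, "'")
  structure(list(name = name, n = length(E), n_excluded = n_exc,
                 mean_E = mean(E),
                 sd_E = if (length(E) > 1L) sd(E) else NA_real_,
                 sem_E = if (length(E) > 1L) sd(E) / sqrt(length(E))
                         else NA_real_,
                 E = E),
            class = "group_summary")
}

#' Compare two cell groups by Welch's t-test
#'
#' Two-sided unequal-variance t-test on the per-cell Young's moduli,
#' with the effect size reported as the percent difference of group
#' means relative to group b. Degenerate zero-variance inputs are
#' handled by convention: equal means give p = 1, distinct means give
#' p = 0 with a `degenerate` flag.
#'
#' @param a,b `group_summary` objects (or numeric vectors of moduli, Pa;
#'   n >= 2 each).
#' @return list of class `group_comparison`: per-group summaries,
#'   `t_statistic`, `df`, `p_value`, `percent_difference`, `degenerate`.
#' @export
compare_groups <- function(a, b) {
  if (is.numeric(a)) a <- analyze_group(a, "a")
  if (is.numeric(b)) b <- analyze_group(b, "b")
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"),
            a$n >= 2L, b$n >= 2L)
  va <- stats::var(a$E); vb <- stats::var(b$E)
  degenerate <- (va == 0 && vb == 0)
  if (degenerate) {
    if (isTRUE(all.equal(a$mean_E, b$mean_E))) {
      tt <- list(statistic = 0, parameter = a$n + b$n - 2, p.value = 1)
    } else {
      tt <- list(statistic = Inf, parameter = a$n + b$n - 2, p.value = 0)
    }
  } else {
    w <- t.test(a$E, b$E, var.equal = FALSE, alternative = "two.sided")
    tt <- list(statistic = unname(w$statistic), parameter = unname(w$parameter),
               p.value = w$p.value)
  }
  structure(list(group_a = a, group_b = b,
                 t_statistic = tt$statistic, df = tt$parameter,
                 p_value = tt$p.value,
                 percent_difference = 100 * (a$mean_E - b$mean_E) / b$mean_E,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(g) sprintf("%s: n=%d, E = %.2f Pa (SD %.2f, SEM %.2f)",
                             g$name, g$n, g$mean_E,
                             g$sd_E %||% NA, g$sem_E %||% NA)
  cat("Welch two-sample comparison of Young's modulus\n")
  cat(" ", fmt(x$group_a), "\n ", fmt(x$group_b), "\n")
  cat(sprintf("  t = %.3f, df = %.1f, two-sided p = %.3g\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  percent difference of means: %.1f%%\n", x$percent_difference))
  invisible(x)
}
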