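# The asymptotic MK test: alpha computed per derived-allele-frequency bin,
# an exponential model fitted across the (trimmed) spectrum, and the
# adaptation rate read off as the fitted value at x = 1. Slightly deleterious
# variants depress alpha(x) at low x only, so the asymptote corrects the
# downward bias of the standard test without choosing a hard cutoff.

#' Per-frequency-bin alpha trajectory
#'
#' For each DAF bin x, alpha(x) = 1 - (Ds/Dn) * (Pn(x)/Ps(x)) using that
#' bin's counts (non-cumulative by default). Bins with Ps(x) = 0 are kept as
#' undefined points with a reason, never dropped silently.
#'
#' @param daf A [daf_table].
#' @param div A [divergence_summary] with `dn > 0`.
#' @param cumulative If `TRUE`, use counts accumulated from the lowest bin
#'   upward instead of per-bin counts.
#' @return An object of class `alpha_trajectory`: a data frame with columns
#'   `x`, `alpha`, `defined`, `reason`.
#' @export
alpha_trajectory <- function(daf, div, cumulative = FALSE) {
  stopifnot(inherits(daf, "daf_table"), inherits(div, "divergence_summary"))
  if (div$dn == 0) stop("no_selected_divergence: Dn = 0, alpha(x) undefined")
  pn <- daf$pn; ps <- daf$ps
  if (cumulative) { pn <- cumsum(pn); ps <- cumsum(ps) }
  defined <- ps > 0
  alpha <- rep(NA_real_, nrow(daf))
  alpha[defined] <- 1 - (div$ds / div$dn) * (pn[defined] / ps[defined])
  out <- data.frame(x = daf$daf, alpha = alpha, defined = defined,
                    reason = ifelse(defined, "", "ps_zero"),
                    stringsAsFactors = FALSE)
  class(out) <- c("alpha_trajectory", "data.frame")
  out
}

#' Trim an alpha trajectory to a frequency interval
#'
#' Removing the highest-frequency bins guards against ancestral-state
#' (polarization) errors, which masquerade as high-frequency derived
#' variants; the default analysis interval is `[0, 0.9]`.
#'
#' @param traj An [alpha_trajectory].
#' @param x_low,x_high Inclusive frequency bounds, `0 <= x_low < x_high <= 1`.
#' @return The trimmed trajectory.
#' @export
trim_trajectory <- function(traj, x_low = 0, x_high = 0.9) {
  stopifnot(inherits(traj, "alpha_trajectory"))
  if (!(x_low >= 0 && x_high <= 1 && x_low < x_high))
    stop("need 0 <= x_low < x_high <= 1")
  out <- traj[traj$x >= x_low & traj$x <= x_high, , drop = FALSE]
  if (sum(out$defined) < 3L)
    stop("insufficient_points: fewer than 3 defined trajectory points remain")
  rownames(out) <- NULL
  class(out) <- c("alpha_trajectory", "data.frame")
  out
}

# For a fixed decay rate c the exponential model is linear in (a, b); solve
# that profile by least squares to seed the nonlinear fit.
profile_ab <- function(x, y, w, c0) {
  z <- exp(-c0 * x)
  fit <- stats::lm.wfit(cbind(1, z), y, w)
  list(a = fit$coefficients[1L], b = fit$coefficients[2L],
       sse = sum(w * fit$residuals^2))
}

#' Fit the asymptotic-MKT exponential model
#'
#' Least-squares fit of `alpha(x) = a + b * exp(-c * x)` to the defined
#' trajectory points, with a restart grid over the decay rate
#' `c in {0.1, 0.5, 1, 2, 5, 10}` (each seeding `a`, `b` by a profiled linear
#' solve) and `c` bounded in (0, 100]. Exponential fits of this kind are
#' multimodal, hence the restarts. If no restart converges, an ordinary
#' linear fit `alpha(x) = a + b * x` is used instead. The reported estimate
#' is the fitted value at x = 1 (`a + b * exp(-c)`, or `a + b` for the linear
#' model), capped at 1 with a note.
#'
#' @param traj An [alpha_trajectory] with at least 3 defined points.
#' @param weights `"unit"` (default; the model treats every bin equally) or
#'   `"count"` to weight bins by their neutral-class counts.
#' @param daf Required only for `weights = "count"`: the source [daf_table].
#' @return A list of class `asymptotic_fit`: `model`
#'   (`"exponential"`/`"linear"`), parameters `a`, `b`, `c` (`c` absent for
#'   linear), `alpha_asymptote`, `sse`, `x_interval`, `converged`, `notes`.
#' @export
fit_asymptotic <- function(traj, weights = c("unit", "count"), daf = NULL) {
  stopifnot(inherits(traj, "alpha_trajectory"))
  weights <- match.arg(weights)
  pts <- traj[traj$defined, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("insufficient_points: need at least 3 defined trajectory points")
  x <- pts$x; y <- pts$alpha
  w <- rep(1, length(x))
  if (weights == "count") {
    if (is.null(daf)) stop("weights = 'count' requires the source daf table")
    w <- daf$ps[match(x, daf$daf)]
    w <- w / mean(w)
  }
  notes <- character(0)
  best <- NULL
  if (length(unique(x)) >= 3L) {
    # The model is linear in (a, b) given c, so the profiled SSE is a smooth
    # 1-D function of c; scan it on a log grid and refine the best bracket.
    # The multimodality of the full 3-D problem lives entirely in this scan.
    scan <- exp(seq(log(1e-4), log(100), length.out = 80))
    scan_sse <- vapply(scan, function(c0) profile_ab(x, y, w, c0)$sse,
                       numeric(1))
    i_best <- which.min(scan_sse)
    bracket <- c(scan[max(1L, i_best - 1L)],
                 scan[min(length(scan), i_best + 1L)])
    c_opt <- stats::optimize(function(c0) profile_ab(x, y, w, c0)$sse,
                             interval = bracket, tol = 1e-12)$minimum
    starts <- unique(c(0.1, 0.5, 1, 2, 5, 10, c_opt))
    for (c0 in starts) {
      st0 <- profile_ab(x, y, w, c0)
      if (is.null(best) || st0$sse < best$sse - 1e-15)
        best <- list(a = st0$a, b = st0$b, cc = c0, sse = st0$sse)
      st <- profile_ab(x, y, w, c0)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a + b * exp(-cc * x),
                          start = list(a = st$a, b = st$b, cc = c0),
                          lower = c(-Inf, -Inf, 1e-6),
                          upper = c(Inf, Inf, 100),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w2) NULL)
      if (is.null(fit)) next
      sse <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-15)
        best <- c(as.list(stats::coef(fit)), list(sse = sse))
    }
  }
  interval <- c(min(traj$x), max(traj$x))
  if (!is.null(best)) {
    # final derivative-free polish from the best restart (the Levenberg-
    # Marquardt step tolerance can stop a hair short of the optimum)
    sse_fn <- function(p) {
      cc <- min(max(p[3L], 1e-6), 100)
      sum(w * (y - p[1L] - p[2L] * exp(-cc * x))^2)
    }
    opt <- tryCatch(stats::optim(c(best$a, best$b, best$cc), sse_fn,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(opt) && opt$value < best$sse)
      best <- list(a = opt$par[1L], b = opt$par[2L],
                   cc = min(max(opt$par[3L], 1e-6), 100), sse = opt$value)
    asym <- best$a + best$b * exp(-best$cc)
    if (asym > 1) { asym <- 1; notes <- add_note(notes, "asymptote_capped") }
    out <- list(model = "exponential", a = unname(best$a), b = unname(best$b),
                c = unname(best$cc), alpha_asymptote = unname(asym),
                sse = best$sse, x_interval = interval, converged = TRUE,
                notes = notes)
  } else {
    lf <- stats::lm.wfit(cbind(1, x), y, w)
    a <- unname(lf$coefficients[1L]); b <- unname(lf$coefficients[2L])
    if (any(is.na(c(a, b))))
      stop("degenerate trajectory: neither exponential nor linear fit possible")
    asym <- a + b
    if (asym > 1) { asym <- 1; notes <- add_note(notes, "asymptote_capped") }
    out <- list(model = "linear", a = a, b = b, alpha_asymptote = asym,
                sse = sum(w * lf$residuals^2), x_interval = interval,
                converged = FALSE, notes = add_note(notes, "linear_fallback"))
  }
  class(out) <- "asymptotic_fit"
  out
}

#' @export
print.asymptotic_fit <- function(x, ...) {
  cat(sprintf("Asymptotic fit (%s): alpha(1) = %.6g over x in [%g, %g]\n",
              x$model, x$alpha_asymptote, x$x_interval[1L], x$x_interval[2L]))
  invisible(x)
}

predict_fit <- function(fit, x) {
  if (fit$model == "exponential") fit$a + fit$b * exp(-fit$c * x)
  else fit$a + fit$b * x
}

#' Parametric-bootstrap confidence interval for the asymptote
#'
#' Redraws each bin's `Pn(x)` and `Ps(x)` as Poisson with mean equal to the
#' observed count, recomputes and refits the trajectory, and reports the
#' percentile 2.5/97.5 interval of the asymptote over `n_boot` replicates.
#' This parametric bootstrap is this package's own CI construction for the
#' asymptotic estimate. Replicates whose fit fails (for example, too few
#' defined bins after resampling) are dropped and counted.
#'
#' @param fit An [fit_asymptotic] result (defines the trimming interval).
#' @param daf,div The source tables.
#' @param n_boot Number of replicates (default 1000); 0 returns a degenerate
#'   interval with note `"no_ci"`.
#' @param seed Integer seed; replicate streams are derived by index, so the
#'   interval is reproducible.
#' @param cumulative Passed through to [alpha_trajectory].
#' @return List with `ci_low`, `ci_high`, `n_failed`, `notes`.
#' @export
asymptote_ci <- function(fit, daf, div, n_boot = 1000L, seed = 1L,
                         cumulative = FALSE) {
  stopifnot(inherits(fit, "asymptotic_fit"))
  if (n_boot == 0L)
    return(list(ci_low = fit$alpha_asymptote, ci_high = fit$alpha_asymptote,
                n_failed = 0L, notes = "no_ci"))
  reps <- rep(NA_real_, n_boot)
  for (r in seq_len(n_boot)) {
    reps[r] <- with_seed(derive_seed(seed, r), {
      pn <- stats::rpois(nrow(daf), daf$pn)
      ps <- stats::rpois(nrow(daf), daf$ps)
      tryCatch({
        d2 <- daf_table(daf$daf, pn, ps, n_sample = attr(daf, "n_sample"))
        tr <- alpha_trajectory(d2, div, cumulative = cumulative)
        tr <- trim_trajectory(tr, fit$x_interval[1L], fit$x_interval[2L])
        fit_asymptotic(tr)$alpha_asymptote
      }, error = function(e) NA_real_)
    })
  }
  ok <- !is.na(reps)
  notes <- character(0)
  if (mean(!ok) > 0.5) notes <- add_note(notes, "ci_unreliable")
  if (!any(ok)) return(list(ci_low = NA_real_, ci_high = NA_real_,
                            n_failed = sum(!ok),
                            notes = add_note(notes, "all_replicates_failed")))
  qs <- stats::quantile(reps[ok], c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = qs[1L], ci_high = qs[2L], n_failed = sum(!ok), notes = notes)
}

# mkt() dispatch target for method = "asymptotic".
mkt_asymptotic <- function(daf, div, x_low = 0, x_high = 0.9, n_boot = 1000L,
                           seed = NULL, cumulative = FALSE) {
  traj <- alpha_trajectory(daf, div, cumulative = cumulative)
  trimmed <- trim_trajectory(traj, x_low, x_high)
  fit <- fit_asymptotic(trimmed)
  ci <- asymptote_ci(fit, daf, div, n_boot = n_boot, seed = seed %||% 1L,
                     cumulative = cumulative)
  notes <- Reduce(add_note, c(fit$notes, ci$notes), character(0))
  keep <- daf$daf >= x_low & daf$daf <= x_high
  res <- structure(list(
    method = "asymptotic",
    alpha = fit$alpha_asymptote,
    p_value = NULL,
    table = c(pn = sum(daf$pn[keep]), ps = sum(daf$ps[keep]),
              dn = div$dn, ds = div$ds),
    cutoff = NA_real_,
    fractions = NULL,
    notes = notes,
    trajectory = trimmed,
    full_trajectory = traj,
    fit = fit,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    n_boot = n_boot, n_boot_failed = ci$n_failed,
    seed = seed
  ), class = c("mkt_asymptotic", "mkt"))
  res
}

#' @export
predict.mkt_asymptotic <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$trajectory$x
       else if (is.list(newdata)) newdata$x else newdata
  predict_fit(object$fit, x)
}

#' @export
residuals.mkt_asymptotic <- function(object, ...) {
  pts <- object$trajectory[object$trajectory$defined, , drop = FALSE]
  pts$alpha - predict_fit(object$fit, pts$x)
}

plot_trajectory <- function(x, ...) {
  traj <- x$full_trajectory %||% x$trajectory
  pts <- traj[traj$defined, , drop = FALSE]
  graphics::plot(pts$x, pts$alpha, pch = 16, xlab = "derived allele frequency x",
                 ylab = expression(alpha(x)), xlim = c(0, 1),
                 main = "Asymptotic MKT", ...)
  xx <- seq(max(1e-3, min(pts$x)), 1, length.out = 200)
  graphics::lines(xx, predict_fit(x$fit, xx), col = "red")
  graphics::abline(h = x$alpha, col = "red", lty = 2)
  graphics::abline(v = x$fit$x_interval, col = "grey40", lty = 3)
  if (!is.null(x$ci_low) && !is.na(x$ci_low))
    graphics::rect(0, x$ci_low, 1, x$ci_high,
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
  invisible(x)
}
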