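# The MK 2x2 framework: Fisher's exact test on the polymorphism/divergence
# contingency table, the point estimate of alpha, and the standard, FWW and
# extended variants. The asymptotic variant lives in asymptotic.R and is
# dispatched through mkt() as well.

#' Two-sided Fisher's exact test for an MK 2x2 table
#'
#' Computes the exact two-sided p-value for the table
#' \preformatted{          polymorphic   divergent
#'  selected      Pn           Dn
#'  neutral       Ps           Ds}
#' by summing the hypergeometric point probabilities that do not exceed the
#' probability of the observed table (with 1e-7 relative slack, the usual
#' convention for exact two-sided tests). Tables with a zero margin carry no
#' information about association; their p-value is defined as 1 and flagged.
#'
#' @param pn,ps,dn,ds Non-negative integer cell counts.
#' @return A list with `p_value` and a character vector `notes` (possibly
#'   containing `"degenerate_margin"`).
#' @examples
#' fisher_exact_2x2(pn = 2, ps = 0, dn = 0, ds = 2)$p_value  # 1/3
#' @export
fisher_exact_2x2 <- function(pn, ps, dn, ds) {
  if (!is_count(c(pn, ps, dn, ds))) stop("cell counts must be non-negative integers")
  pn <- round(pn); ps <- round(ps); dn <- round(dn); ds <- round(ds)
  r1 <- pn + dn; r2 <- ps + ds; c1 <- pn + ps; c2 <- dn + ds
  if (min(r1, r2, c1, c2) == 0L)
    return(list(p_value = 1, notes = "degenerate_margin"))
  n <- r1 + r2
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[match(pn, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(p, 1)
  if (1 - p < 1e-12) p <- 1   # guard against accumulated rounding
  list(p_value = p, notes = character(0))
}

#' Point estimate of the fraction of adaptive substitutions
#'
#' alpha = 1 - (Ds * Pn) / (Dn * Ps). Under strict neutrality of segregating
#' sites the polymorphism and divergence ratios agree and alpha = 0; an excess
#' of selected divergence gives alpha > 0. The estimate is undefined (NA,
#' flagged) when Dn = 0 or Ps = 0.
#'
#' @param pn,ps,dn,ds Table counts (see [fisher_exact_2x2]).
#' @return List with `alpha` (NA when undefined) and `notes`.
#' @examples
#' alpha_point(pn = 10, ps = 10, dn = 20, ds = 10)$alpha  # 0.5
#' @export
alpha_point <- function(pn, ps, dn, ds) {
  if (dn == 0 || ps == 0)
    return(list(alpha = NA_real_, notes = "alpha_undefined"))
  list(alpha = 1 - (ds * pn) / (dn * ps), notes = character(0))
}

mkt_result <- function(method, pn, ps, dn, ds, cutoff = NA_real_,
                       fractions = NULL, notes = character(0), extra = list()) {
  ap <- alpha_point(pn, ps, dn, ds)
  fe <- fisher_exact_2x2(round(pn), round(ps), round(dn), round(ds))
  structure(c(list(
    method = method,
    alpha = ap$alpha,
    p_value = if (is.na(ap$alpha) && length(fe$notes)) NA_real_ else fe$p_value,
    table = c(pn = pn, ps = ps, dn = dn, ds = ds),
    cutoff = cutoff,
    fractions = fractions,
    notes = Reduce(add_note, c(ap$notes, fe$notes, notes), character(0))
  ), extra), class = "mkt")
}

mkt_standard <- function(daf, div) {
  mkt_result("standard", sum(daf$pn), sum(daf$ps), div$dn, div$ds)
}

mkt_fww <- function(daf, div, cutoff = 0.05) {
  if (cutoff < 0 || cutoff >= 1) stop("FWW cutoff must lie in [0, 1)")
  keep <- daf$daf >= cutoff
  mkt_result("fww", sum(daf$pn[keep]), sum(daf$ps[keep]), div$dn, div$ds,
             cutoff = cutoff)
}

mkt_emkt <- function(daf, div, cutoff = 0.05) {
  if (cutoff <= 0 || cutoff >= 1) stop("eMKT cutoff must lie in (0, 1)")
  low <- daf$daf < cutoff
  pn_l <- sum(daf$pn[low]);  pn_h <- sum(daf$pn[!low])
  ps_l <- sum(daf$ps[low]);  ps_h <- sum(daf$ps[!low])
  ps_tot <- ps_l + ps_h
  notes <- character(0)
  if (ps_h == 0) {
    res <- mkt_result("emkt", pn_l + pn_h, ps_tot, div$dn, div$ds,
                      cutoff = cutoff, notes = "partition_undefined")
    res$alpha <- NA_real_
    return(res)
  }
  # Expected number of neutral selected-class variants below the cutoff,
  # borrowing the neutral-class spectrum shape; the observed excess is the
  # weakly deleterious load.
  expected <- pn_h * ps_l / ps_h
  wd <- max(0, pn_l - expected)
  if (expected > pn_l) notes <- add_note(notes, "expected_exceeds_observed")
  pn_neutral <- pn_h + min(pn_l, expected)

  fractions <- NULL
  if (!is.na(div$m_n) && !is.na(div$m_s) && div$m_n > 0 && ps_tot > 0) {
    f <- (div$m_s * pn_neutral) / (div$m_n * ps_tot)
    b <- (div$m_s * wd) / (div$m_n * ps_tot)
    if (f < 0 || f > 1 || b < 0 || b > 1) notes <- add_note(notes, "fractions_clamped")
    f <- min(max(f, 0), 1); b <- min(max(b, 0), 1)
    d <- 1 - f - b
    if (d < 0) {
      notes <- add_note(notes, "fractions_clamped")
      s <- f + b; f <- f / s; b <- b / s; d <- 0
    }
    fractions <- c(f = f, b = b, d = d)
  } else if (is.na(div$m_n) || is.na(div$m_s)) {
    notes <- add_note(notes, "site_totals_unknown")
  }

  pn_round <- round(pn_neutral)
  if (abs(pn_round - pn_neutral) > 1e-9) notes <- add_note(notes, "rounded_for_fisher")
  res <- mkt_result("emkt", pn_round, ps_tot, div$dn, div$ds, cutoff = cutoff,
                    fractions = fractions, notes = notes,
                    extra = list(pn_neutral = pn_neutral,
                                 weakly_deleterious = wd))
  # alpha uses the unrounded partition; only the Fisher table is rounded
  res$alpha <- if (div$dn == 0 || ps_tot == 0) NA_real_ else
    1 - (div$ds * pn_neutral) / (div$dn * ps_tot)
  if (is.na(res$alpha)) res$notes <- add_note(res$notes, "alpha_undefined")
  res$table[["pn"]] <- pn_neutral
  res
}

#' Fit a McDonald-Kreitman test
#'
#' The single entry point for the four MK-derived estimators of the fraction
#' of adaptive nonsynonymous substitutions, alpha:
#' \describe{
#'   \item{`standard`}{the original 2x2 test on total polymorphism and
#'     divergence counts.}
#'   \item{`fww`}{the Fay-Wyckoff-Wu correction: all bins with derived allele
#'     frequency below `cutoff` are discarded from both site classes before
#'     the standard test.}
#'   \item{`emkt`}{the extended test: the selected-class polymorphism below
#'     `cutoff` is partitioned into neutral and weakly deleterious fractions
#'     using the neutral-class spectrum, and alpha is computed from the
#'     neutral part only. When site totals `m_n`/`m_s` are available the
#'     selection-regime fractions f (neutral), b (weakly deleterious) and
#'     d (strongly deleterious) are also estimated.}
#'   \item{`asymptotic`}{alpha is computed per frequency bin, an exponential
#'     model `alpha(x) = a + b * exp(-c * x)` is fitted over the trimmed
#'     interval `[x_low, x_high]`, and the estimate is the fitted value at
#'     x = 1, with a parametric-bootstrap 95% CI.}
#' }
#'
#' @param daf A [daf_table] (or a [gene_record], whose tables are used).
#' @param div A [divergence_summary]; ignored when `daf` is a gene record.
#' @param method One of `"standard"`, `"fww"`, `"emkt"`, `"asymptotic"`.
#' @param cutoff Low-frequency cutoff for `fww` and `emkt` (default 0.05).
#' @param x_low,x_high Trajectory trimming interval for `asymptotic`
#'   (default `[0, 0.9]`; high-frequency bins are prone to polarization
#'   error).
#' @param n_boot Bootstrap replicates for the asymptotic CI (default 1000;
#'   0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param cumulative Use cumulative frequency bins for the asymptotic
#'   trajectory instead of the default per-bin values.
#' @return An object of class `mkt` (for `asymptotic`, subclass
#'   `mkt_asymptotic`) with components `method`, `alpha`, `p_value`, `table`,
#'   `cutoff`, `fractions`, `notes`, and for the asymptotic fit `trajectory`,
#'   `fit`, `ci_low`, `ci_high`. Supports `print`, `summary`, `coef`,
#'   `confint`, `plot` and (asymptotic only) `predict`/`residuals`.
#' @examples
#' d <- daf_table(c(0.1, 0.5), pn = c(8, 2), ps = c(2, 8))
#' v <- divergence_summary(dn = 10, ds = 10)
#' mkt(d, v, method = "fww", cutoff = 0.25)
#' @export
mkt <- function(daf, div, method = c("standard", "fww", "emkt", "asymptotic"),
                cutoff = 0.05, x_low = 0, x_high = 0.9, n_boot = 1000L,
                seed = NULL, cumulative = FALSE) {
  if (inherits(daf, "gene_record")) {
    div <- daf$div; daf <- daf$daf
  }
  stopifnot(inherits(daf, "daf_table"), inherits(div, "divergence_summary"))
  method <- match.arg(method)
  switch(method,
         standard = mkt_standard(daf, div),
         fww = mkt_fww(daf, div, cutoff),
         emkt = mkt_emkt(daf, div, cutoff),
         asymptotic = mkt_asymptotic(daf, div, x_low = x_low, x_high = x_high,
                                     n_boot = n_boot, seed = seed,
                                     cumulative = cumulative))
}

#' @export
print.mkt <- function(x, digits = 4, ...) {
  label <- c(standard = "Standard MKT", fww = "FWW-corrected MKT",
             emkt = "Extended MKT", asymptotic = "Asymptotic MKT")[x$method]
  cat(label, "\n")
  tab <- x$table
  cat(sprintf("  table: Pn = %g, Ps = %g, Dn = %g, Ds = %g\n",
              tab[["pn"]], tab[["ps"]], tab[["dn"]], tab[["ds"]]))
  if (!is.na(x$cutoff %||% NA)) cat("  cutoff:", x$cutoff, "\n")
  cat("  alpha =", ifelse(is.na(x$alpha), "undefined",
                          format(x$alpha, digits = digits)))
  if (!is.null(x$ci_low))
    cat(sprintf("  [95%% CI %s, %s]", format(x$ci_low, digits = digits),
                format(x$ci_high, digits = digits)))
  if (!is.null(x$p_value))
    cat("   p =", ifelse(is.na(x$p_value), "undefined",
                         format(x$p_value, digits = digits)))
  cat("\n")
  if (!is.null(x$fractions))
    cat(sprintf("  regimes: f (neutral) = %s, b (weakly del.) = %s, d (strongly del.) = %s\n",
                format(x$fractions[["f"]], digits = digits),
                format(x$fractions[["b"]], digits = digits),
                format(x$fractions[["d"]], digits = digits)))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mkt <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$fit)) {
    fit <- object$fit
    cat(sprintf("  fit: %s model over x in [%g, %g]%s\n", fit$model,
                fit$x_interval[1L], fit$x_interval[2L],
                if (isTRUE(fit$converged)) "" else " (not converged)"))
    if (fit$model == "exponential")
      cat(sprintf("       a = %.6g, b = %.6g, c = %.6g\n", fit$a, fit$b, fit$c))
    else
      cat(sprintf("       intercept = %.6g, slope = %.6g\n", fit$a, fit$b))
  }
  invisible(object)
}

#' @export
coef.mkt <- function(object, ...) {
  out <- c(alpha = object$alpha)
  if (!is.null(object$fit) && object$fit$model == "exponential")
    out <- c(out, a = object$fit$a, b = object$fit$b, c = object$fit$c)
  out
}

#' @export
confint.mkt <- function(object, parm = "alpha", level = 0.95, ...) {
  if (is.null(object$ci_low))
    stop("no confidence interval available; use method = 'asymptotic' or ",
         "bootstrap_alpha() for cohort-level intervals")
  out <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
                dimnames = list("alpha", c("2.5 %", "97.5 %")))
  out
}

#' @export
plot.mkt <- function(x, ...) {
  if (!is.null(x$trajectory)) return(plot_trajectory(x, ...))
  tab <- x$table
  graphics::barplot(rbind(c(tab[["pn"]], tab[["dn"]]), c(tab[["ps"]], tab[["ds"]])),
                    beside = TRUE, names.arg = c("polymorphic", "divergent"),
                    legend.text = c("selected (N)", "neutral (S)"),
                    main = sprintf("%s: alpha = %s", x$method,
                                   format(x$alpha, digits = 3)), ...)
  invisible(x)
}
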