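# Multi-gene analysis: concatenation of spectra, stratified association and
# heterogeneity tests across genes, bootstrap sampling distributions of alpha
# and group-versus-group comparisons.

#' Rebin a DAF table onto a fixed 20-bin grid
#'
#' Maps each frequency bin into the grid of 20 intervals of width 0.05
#' (`((j-1)/20, j/20]`), represented by their midpoints. Used to make genes
#' sampled at different depths commensurable before concatenation.
#'
#' @param daf A [daf_table].
#' @param n_bins Number of equal-width bins (default 20).
#' @return A [daf_table] on the common grid (with `n_sample` dropped).
#' @export
rebin_daf <- function(daf, n_bins = 20L) {
  stopifnot(inherits(daf, "daf_table"))
  idx <- pmin(ceiling(daf$daf * n_bins - 1e-9), n_bins)
  pn <- vapply(seq_len(n_bins), function(j) sum(daf$pn[idx == j]), numeric(1))
  ps <- vapply(seq_len(n_bins), function(j) sum(daf$ps[idx == j]), numeric(1))
  daf_table((seq_len(n_bins) - 0.5) / n_bins, pn, ps, n_sample = NA_integer_)
}

same_grid <- function(genes) {
  g1 <- genes[[1L]]$daf$daf
  all(vapply(genes, function(g)
    length(g$daf$daf) == length(g1) && all(abs(g$daf$daf - g1) < 1e-9),
    logical(1)))
}

#' Concatenate genes into a single pooled record
#'
#' Sums the DAF spectra bin-wise and the divergence counts and site totals
#' across genes, so the selective regime of the whole set is analyzed
#' instead of gene by gene. Genes whose frequency grids differ (for example,
#' different sample depths) are first rebinned onto the common 20-bin grid
#' of [rebin_daf].
#'
#' @param genes Non-empty list of [gene_record] objects.
#' @param gene_id Identifier for the pooled record.
#' @return A [gene_record] whose metadata records `n_genes`.
#' @export
concatenate_genes <- function(genes, gene_id = "concatenated") {
  if (length(genes) == 0L) stop("cannot concatenate an empty gene list")
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_record")))
  if (!same_grid(genes))
    genes <- lapply(genes, function(g) {
      g$daf <- rebin_daf(g$daf); g
    })
  d1 <- genes[[1L]]$daf
  pn <- Reduce(`+`, lapply(genes, function(g) g$daf$pn))
  ps <- Reduce(`+`, lapply(genes, function(g) g$daf$ps))
  sum_or_na <- function(x) if (anyNA(x)) NA_real_ else sum(x)
  gene_record(
    gene_id = gene_id,
    daf = daf_table(d1$daf, pn, ps, n_sample = attr(d1, "n_sample")),
    div = divergence_summary(
      dn = sum(vapply(genes, function(g) g$div$dn, numeric(1))),
      ds = sum(vapply(genes, function(g) g$div$ds, numeric(1))),
      m_n = sum_or_na(vapply(genes, function(g) g$div$m_n, numeric(1))),
      m_s = sum_or_na(vapply(genes, function(g) g$div$m_s, numeric(1)))),
    metadata = list(n_genes = length(genes)))
}

gene_2x2 <- function(g) {
  matrix(c(sum(g$daf$pn), sum(g$daf$ps), g$div$dn, g$div$ds), nrow = 2,
         dimnames = list(class = c("selected", "neutral"),
                         type = c("polymorphic", "divergent")))
}

#' Stratified 2x2 tests across genes
#'
#' Treats each gene's MK table as one stratum. `variant = "common"` is the
#' classic Cochran-Mantel-Haenszel chi-square test of common association
#' (df = 1, no continuity correction), delegated to
#' [stats::mantelhaen.test()]; `variant = "heterogeneity"` is the
#' Breslow-Day test of odds-ratio homogeneity with Tarone's correction
#' (df = K - 1), which asks whether selection acts heterogeneously among the
#' analyzed genes. Strata with a zero margin are uninformative and dropped
#' with a warning.
#'
#' @param genes List of at least two [gene_record] objects.
#' @param variant `"common"` or `"heterogeneity"`.
#' @return A list of class `cmh_result`: `statistic`, `df`, `p_value`,
#'   `k_strata`, `variant`, and for the heterogeneity variant the
#'   Mantel-Haenszel `common_or`.
#' @export
cmh_test <- function(genes, variant = c("common", "heterogeneity")) {
  variant <- match.arg(variant)
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_record")))
  tabs <- lapply(genes, gene_2x2)
  ok <- vapply(tabs, function(t)
    min(rowSums(t)) > 0 && min(colSums(t)) > 0, logical(1))
  if (any(!ok))
    warning(sum(!ok), " gene(s) with a degenerate 2x2 table dropped from the ",
            "stratified test")
  tabs <- tabs[ok]
  if (length(tabs) < 2L)
    stop("need at least 2 genes with nondegenerate tables")
  k <- length(tabs)
  if (variant == "common") {
    arr <- array(unlist(tabs), dim = c(2, 2, k))
    ht <- stats::mantelhaen.test(arr, correct = FALSE)
    out <- list(statistic = unname(ht$statistic), df = 1L,
                p_value = unname(ht$p.value), k_strata = k,
                variant = "common")
  } else {
    bd <- breslow_day_tarone(tabs)
    out <- list(statistic = bd$statistic, df = k - 1L, p_value = bd$p_value,
                k_strata = k, variant = "heterogeneity",
                common_or = bd$common_or)
  }
  class(out) <- "cmh_result"
  out
}

#' @export
print.cmh_result <- function(x, ...) {
  lab <- if (x$variant == "common")
    "Cochran-Mantel-Haenszel test of common association"
  else "Breslow-Day-Tarone test of odds-ratio heterogeneity"
  cat(sprintf("%s\n  X-squared = %.4g, df = %d, p = %.4g (%d strata)\n",
              lab, x$statistic, x$df, x$p_value, x$k_strata))
  invisible(x)
}

# Breslow-Day statistic with Tarone adjustment. For each stratum the expected
# a-cell under the Mantel-Haenszel common odds ratio solves a quadratic in a.
breslow_day_tarone <- function(tabs) {
  a <- vapply(tabs, function(t) t[1, 1], numeric(1))
  b <- vapply(tabs, function(t) t[1, 2], numeric(1))
  cc <- vapply(tabs, function(t) t[2, 1], numeric(1))
  d <- vapply(tabs, function(t) t[2, 2], numeric(1))
  n <- a + b + cc + d
  or_mh <- sum(a * d / n) / sum(b * cc / n)
  r1 <- a + b; c1 <- a + cc
  expected <- numeric(length(a)); vari <- numeric(length(a))
  for (k in seq_along(a)) {
    if (abs(or_mh - 1) < 1e-12) {
      A <- r1[k] * c1[k] / n[k]
    } else {
      qa <- 1 - or_mh
      qb <- (n[k] - r1[k] - c1[k]) + or_mh * (r1[k] + c1[k])
      qc <- -or_mh * r1[k] * c1[k]
      disc <- sqrt(qb^2 - 4 * qa * qc)
      roots <- c((-qb + disc) / (2 * qa), (-qb - disc) / (2 * qa))
      valid <- roots[roots > 0 & roots < r1[k] & roots < c1[k] &
                       (n[k] - r1[k] - c1[k] + roots) > 0]
      if (!length(valid)) stop("no admissible expected cell in stratum ", k)
      A <- valid[1L]
    }
    expected[k] <- A
    vari[k] <- 1 / (1 / A + 1 / (r1[k] - A) + 1 / (c1[k] - A) +
                      1 / (n[k] - r1[k] - c1[k] + A))
  }
  x2 <- sum((a - expected)^2 / vari)
  x2t <- x2 - sum(a - expected)^2 / sum(vari)
  list(statistic = x2t, p_value = stats::pchisq(x2t, length(a) - 1L,
                                                lower.tail = FALSE),
       common_or = or_mh)
}

estimate_alpha <- function(gene, method, cutoff, x_low = 0, x_high = 0.9) {
  res <- switch(method,
                standard = mkt_standard(gene$daf, gene$div),
                fww = mkt_fww(gene$daf, gene$div, cutoff),
                emkt = mkt_emkt(gene$daf, gene$div, cutoff),
                asymptotic = tryCatch(
                  mkt_asymptotic(gene$daf, gene$div, x_low = x_low,
                                 x_high = x_high, n_boot = 0L),
                  error = function(e) list(alpha = NA_real_)))
  res$alpha
}

#' Bootstrap sampling distribution of alpha over a gene set
#'
#' Each replicate draws `sample_size` genes with replacement, concatenates
#' them and estimates alpha with the chosen method; the summary reports the
#' replicate mean, SD and percentile 95% CI. Replicate RNG streams are
#' derived from `seed` by replicate index and genes are sorted by id first,
#' so results do not depend on the input ordering. Replicates with undefined
#' alpha are dropped and counted; more than 20% dropped flags the result.
#'
#' @param genes List of [gene_record] objects.
#' @param method `"standard"`, `"fww"`, `"emkt"` or `"asymptotic"`.
#' @param cutoff Low-frequency cutoff for `fww`/`emkt`.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param sample_size Genes drawn per replicate (default: the group size).
#' @param seed Integer seed.
#' @param x_low,x_high Trimming interval when `method = "asymptotic"`.
#' @return A list of class `mkt_boot`: `alphas` (length `n_reps`, `NA` for
#'   failed replicates), `mean`, `sd`, `ci_low`, `ci_high`, `n_failed`,
#'   `method`, `cutoff`, `sample_size`, `seed`, `notes`.
#' @export
bootstrap_alpha <- function(genes, method = "standard", cutoff = 0.05,
                            n_reps = 100L, sample_size = length(genes),
                            seed = 1L, x_low = 0, x_high = 0.9) {
  if (n_reps < 1L || sample_size < 1L)
    stop("n_reps and sample_size must be >= 1")
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_record")))
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  genes <- genes[order(ids)]
  if (!same_grid(genes))
    genes <- lapply(genes, function(g) { g$daf <- rebin_daf(g$daf); g })
  # matrix form for fast replicate concatenation
  pn_mat <- do.call(cbind, lapply(genes, function(g) g$daf$pn))
  ps_mat <- do.call(cbind, lapply(genes, function(g) g$daf$ps))
  dn_vec <- vapply(genes, function(g) g$div$dn, numeric(1))
  ds_vec <- vapply(genes, function(g) g$div$ds, numeric(1))
  mn_vec <- vapply(genes, function(g) g$div$m_n, numeric(1))
  ms_vec <- vapply(genes, function(g) g$div$m_s, numeric(1))
  grid <- genes[[1L]]$daf$daf
  n_samp <- attr(genes[[1L]]$daf, "n_sample")

  alphas <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    idx <- with_seed(derive_seed(seed, r),
                     sample.int(length(genes), sample_size, replace = TRUE))
    daf <- daf_table(grid, rowSums(pn_mat[, idx, drop = FALSE]),
                     rowSums(ps_mat[, idx, drop = FALSE]), n_sample = n_samp)
    div <- divergence_summary(sum(dn_vec[idx]), sum(ds_vec[idx]),
                              m_n = if (anyNA(mn_vec[idx])) NA_real_ else sum(mn_vec[idx]),
                              m_s = if (anyNA(ms_vec[idx])) NA_real_ else sum(ms_vec[idx]))
    alphas[r] <- estimate_alpha(list(daf = daf, div = div), method, cutoff,
                                x_low, x_high)
  }
  ok <- !is.na(alphas)
  notes <- character(0)
  if (mean(!ok) > 0.2) notes <- add_note(notes, "many_replicates_undefined")
  qs <- if (any(ok)) stats::quantile(alphas[ok], c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(alphas = alphas,
                 mean = if (any(ok)) mean(alphas[ok]) else NA_real_,
                 sd = if (sum(ok) > 1L) stats::sd(alphas[ok]) else 0,
                 ci_low = qs[1L], ci_high = qs[2L],
                 n_reps = n_reps, n_failed = sum(!ok),
                 method = method, cutoff = cutoff,
                 sample_size = sample_size, seed = seed, notes = notes),
            class = "mkt_boot")
}

#' @export
print.mkt_boot <- function(x, digits = 4, ...) {
  cat(sprintf(paste0("Bootstrap alpha (%s%s): mean = %s, sd = %s, ",
                     "95%% CI [%s, %s]\n  %d replicates of %d genes",
                     " (%d failed), seed %d\n"),
              x$method,
              ifelse(is.na(x$cutoff), "", sprintf(", cutoff %g", x$cutoff)),
              format(x$mean, digits = digits), format(x$sd, digits = digits),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              x$n_reps, x$sample_size, x$n_failed, x$seed))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = ", "), "\n")
  invisible(x)
}

#' Compare the adaptation rate of two gene sets
#'
#' Runs [bootstrap_alpha] on each group with shared settings but independent
#' seeded streams, and reports per-group summaries together with the
#' replicate-wise difference (group A minus group B) and its percentile 95%
#' CI. Comparing a gene subset against the whole genome is the special case
#' `compare_groups(subset, full_dataset, ...)`.
#'
#' @param group_a,group_b Non-empty lists of [gene_record] objects.
#' @param labels Length-2 character vector naming the groups.
#' @param method,cutoff,n_reps,sample_size,seed As in [bootstrap_alpha];
#'   `sample_size = NULL` uses each group's own size.
#' @return A list of class `mkt_comparison`: per-group `mkt_boot` objects
#'   `boot_a`, `boot_b`, the `difference` summary (mean, sd, `ci_low`,
#'   `ci_high`), `labels` and settings.
#' @export
compare_groups <- function(group_a, group_b, labels = c("A", "B"),
                           method = "standard", cutoff = 0.05,
                           n_reps = 100L, sample_size = NULL, seed = 1L) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  sz_a <- sample_size %||% length(group_a)
  sz_b <- sample_size %||% length(group_b)
  boot_a <- bootstrap_alpha(group_a, method = method, cutoff = cutoff,
                            n_reps = n_reps, sample_size = sz_a, seed = seed)
  boot_b <- bootstrap_alpha(group_b, method = method, cutoff = cutoff,
                            n_reps = n_reps, sample_size = sz_b,
                            seed = derive_seed(seed, 1000003L))
  diffs <- boot_a$alphas - boot_b$alphas
  ok <- !is.na(diffs)
  qs <- if (any(ok)) stats::quantile(diffs[ok], c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(labels = labels, boot_a = boot_a, boot_b = boot_b,
                 difference = list(
                   mean = if (any(ok)) mean(diffs[ok]) else NA_real_,
                   sd = if (sum(ok) > 1L) stats::sd(diffs[ok]) else 0,
                   ci_low = qs[1L], ci_high = qs[2L]),
                 method = method, cutoff = cutoff, n_reps = n_reps,
                 seed = seed),
            class = "mkt_comparison")
}

#' @export
print.mkt_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap comparison (%s, %d replicates)\n", x$method, x$n_reps))
  for (i in 1:2) {
    b <- if (i == 1) x$boot_a else x$boot_b
    cat(sprintf("  %s: alpha mean = %s +/- SD %s, 95%% CI [%s, %s]\n",
                x$labels[i], format(b$mean, digits = digits),
                format(b$sd, digits = digits),
                format(b$ci_low, digits = digits),
                format(b$ci_high, digits = digits)))
  }
  d <- x$difference
  cat(sprintf("  difference (%s - %s): %s, 95%% CI [%s, %s]\n",
              x$labels[1], x$labels[2], format(d$mean, digits = digits),
              format(d$ci_low, digits = digits),
              format(d$ci_high, digits = digits)))
  invisible(x)
}

#' Filter a gene dataset by metadata predicates
#'
#' Combines an id list, a chromosome filter and a minimum recombination rate
#' (strictly greater than the threshold, matching the convention of
#' selecting genes with recombination "higher than" a value). Order is
#' preserved.
#'
#' @param genes List of [gene_record] objects.
#' @param min_rec Keep genes with `metadata$recombination_rate > min_rec`.
#' @param chromosome Keep genes whose `metadata$chromosome` is in this set.
#' @param ids Keep genes whose `gene_id` is in this set; unknown ids produce
#'   a warning.
#' @param strict If `TRUE`, genes lacking a metadata key referenced by an
#'   active predicate raise an error; otherwise they are dropped silently.
#' @return The filtered list of gene records.
#' @export
filter_genes <- function(genes, min_rec = NULL, chromosome = NULL, ids = NULL,
                         strict = FALSE) {
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_record")))
  keep <- rep(TRUE, length(genes))
  if (!is.null(ids)) {
    all_ids <- vapply(genes, `[[`, character(1), "gene_id")
    unknown <- setdiff(ids, all_ids)
    if (length(unknown))
      warning("unknown gene id(s): ", paste(unknown, collapse = ", "))
    keep <- keep & all_ids %in% ids
  }
  meta_pred <- function(key, pred) {
    vapply(genes, function(g) {
      v <- g$metadata[[key]]
      if (is.null(v)) {
        if (strict) stop("gene ", g$gene_id, " lacks metadata key '", key, "'")
        return(FALSE)
      }
      pred(v)
    }, logical(1))
  }
  if (!is.null(min_rec))
    keep <- keep & meta_pred("recombination_rate",
                             function(v) as.numeric(v) > min_rec)
  if (!is.null(chromosome))
    keep <- keep & meta_pred("chromosome", function(v) v %in% chromosome)
  genes[keep]
}
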