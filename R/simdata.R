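# Seeded generators for every input the package consumes: single genes under
# parameterized selection regimes, multi-gene cohorts with metadata, and toy
# alignments with planted variants whose expected spectrum is known by
# construction. The generators draw expected site-frequency spectra with
# Poisson noise (calibrated truth, not genealogical realism).

#' Selection-regime parameters for the gene simulator
#'
#' The generative model behind [simulate_gene]: neutral-class variants follow
#' the standard neutral spectrum (expected count at derived count i
#' proportional to 1/i, scaled by `theta_s * m_s`); selected sites are a
#' mixture of a neutral fraction `f` (same spectrum shape, scaled by
#' `m_n/m_s`), a weakly deleterious fraction `b` (spectrum skewed toward low
#' frequency, proportional to 1/i^(1+weak_skew), contributing no divergence)
#' and a strongly deleterious fraction `d` (contributing neither polymorphism
#' nor divergence). Neutral divergence is Poisson with mean `ds_mean`;
#' selected divergence has mean `ds_mean * (m_n/m_s) * f / (1 - alpha_true)`,
#' so that a fraction `alpha_true` of selected fixations is adaptive.
#'
#' @param n_sample Chromosomes sampled (spectrum depth). Default 20.
#' @param m_n,m_s Numbers of selected and neutral sites (defaults 1200 and
#'   400, a typical single-gene CDS under Nei-Gojobori counting).
#' @param theta_s Neutral pairwise diversity per site (default 0.02, a
#'   Drosophila-like value).
#' @param f,b,d Fractions of selected sites that are effectively neutral,
#'   weakly deleterious and strongly deleterious; must sum to 1.
#' @param weak_skew Low-frequency skew exponent of the weakly deleterious
#'   spectrum (default 1, i.e. proportional to 1/i^2).
#' @param alpha_true Fraction of selected divergence that is adaptive, in
#'   [0, 1).
#' @param ds_mean Expected neutral divergence count (default 40).
#' @return A list of class `regime_params`.
#' @export
regime_params <- function(n_sample = 20L, m_n = 1200, m_s = 400,
                          theta_s = 0.02, f = 1, b = 0, d = 0,
                          weak_skew = 1, alpha_true = 0, ds_mean = 40) {
  if (abs(f + b + d - 1) > 1e-9) stop("f + b + d must equal 1")
  if (any(c(f, b, d) < 0) || any(c(f, b, d) > 1))
    stop("regime fractions must lie in [0, 1]")
  if (alpha_true < 0 || alpha_true >= 1) stop("alpha_true must lie in [0, 1)")
  if (n_sample < 2L) stop("n_sample must be >= 2")
  structure(list(n_sample = as.integer(n_sample), m_n = m_n, m_s = m_s,
                 theta_s = theta_s, f = f, b = b, d = d,
                 weak_skew = weak_skew, alpha_true = alpha_true,
                 ds_mean = ds_mean),
            class = "regime_params")
}

# Expected per-bin counts of the generator; exposed for calibration tests.
regime_expectations <- function(p) {
  i <- seq_len(p$n_sample - 1L)
  neutral <- p$theta_s * p$m_s / i
  # weak-class spectrum ~ 1/i^(1+skew), normalized so its total expected
  # count equals the total of the neutral shape (b is then comparable to f)
  skew_shape <- 1 / i^(1 + p$weak_skew)
  skew <- skew_shape * sum(neutral) / sum(skew_shape)
  ratio <- p$m_n / p$m_s
  list(ps = neutral,
       pn = ratio * (p$f * neutral + p$b * skew),
       ds = p$ds_mean,
       dn = p$ds_mean * ratio * p$f / (1 - p$alpha_true))
}

#' Simulate one gene under a selection regime
#'
#' Draws Poisson counts around the expectations of [regime_params] (see its
#' details for the generative model). The generative expectations are stored
#' in the record's metadata for downstream calibration checks.
#'
#' @param params A [regime_params] object.
#' @param seed Integer seed.
#' @param gene_id Identifier for the record.
#' @param metadata Extra metadata entries (merged with the generative ones).
#' @return A [gene_record].
#' @export
simulate_gene <- function(params, seed = 1L, gene_id = "sim_gene",
                          metadata = list()) {
  stopifnot(inherits(params, "regime_params"))
  ex <- regime_expectations(params)
  with_seed(seed, {
    pn <- stats::rpois(length(ex$pn), ex$pn)
    ps <- stats::rpois(length(ex$ps), ex$ps)
    dn <- stats::rpois(1L, ex$dn)
    ds <- stats::rpois(1L, ex$ds)
    gene_record(
      gene_id = gene_id,
      daf = daf_table(seq_len(params$n_sample - 1L) / params$n_sample,
                      pn, ps, n_sample = params$n_sample),
      div = divergence_summary(dn, ds, m_n = params$m_n, m_s = params$m_s),
      metadata = c(metadata,
                   list(alpha_true = params$alpha_true,
                        expected_pn = sum(ex$pn), expected_ps = sum(ex$ps),
                        expected_dn = ex$dn, expected_ds = ex$ds)))
  })
}

#' Named regime presets
#'
#' `"neutral"`: all selected sites effectively neutral, no adaptation.
#' `"adaptive"`: no deleterious load, half of selected divergence adaptive.
#' `"deleterious"`: a planted weakly (and strongly) deleterious load that
#' biases the standard test downward (sampled at depth 40 so the default
#' 0.05 cutoff isolates singletons).
#' `"figure2_high"` / `"figure2_genome"`: two otherwise identical regimes
#' with true alpha 0.6 and 0.44, emulating a high-recombination gene set
#' versus the genome-wide background.
#'
#' @param preset Preset name.
#' @return A [regime_params] object.
#' @export
regime_preset <- function(preset = c("neutral", "adaptive", "deleterious",
                                     "figure2_high", "figure2_genome")) {
  preset <- match.arg(preset)
  switch(preset,
         neutral = regime_params(),
         adaptive = regime_params(alpha_true = 0.5),
         deleterious = regime_params(n_sample = 40L, f = 0.55, b = 0.25,
                                     d = 0.20, alpha_true = 0.3),
         figure2_high = regime_params(alpha_true = 0.6),
         figure2_genome = regime_params(alpha_true = 0.44))
}

#' Simulate a multi-gene cohort
#'
#' Generates `k` genes from `params`, with chromosome labels drawn uniformly
#' from `chromosomes` and recombination rates uniform over `rec_range`
#' (cM/Mb), enabling metadata filtering and group comparisons.
#'
#' @param k Number of genes.
#' @param params A [regime_params] object (or preset name).
#' @param seed Integer seed; per-gene streams are derived by index.
#' @param prefix Gene-id prefix.
#' @param chromosomes Chromosome label pool.
#' @param rec_range Length-2 range of recombination rates.
#' @return List of [gene_record] objects.
#' @export
simulate_cohort <- function(k, params = regime_params(), seed = 1L,
                            prefix = "g",
                            chromosomes = c("2L", "2R", "3L", "3R", "X"),
                            rec_range = c(0, 15)) {
  if (k < 1L) stop("k must be >= 1")
  if (is.character(params)) params <- regime_preset(params)
  lapply(seq_len(k), function(i) {
    md <- with_seed(derive_seed(seed, 2L * i), list(
      chromosome = sample(chromosomes, 1L),
      recombination_rate = round(stats::runif(1L, rec_range[1L], rec_range[2L]), 3)))
    simulate_gene(params, seed = derive_seed(seed, 2L * i + 1L),
                  gene_id = sprintf("%s%04d", prefix, i), metadata = md)
  })
}

# --- toy alignments with planted variants --------------------------------

TOY_EVENTS <- c("syn-poly", "nonsyn-poly", "syn-fixed", "nonsyn-fixed",
                "multiallelic", "unpolarizable", "missing-N")

#' Build a toy alignment with planted variants
#'
#' Constructs an alignment over a backbone of identical `TTT` codons in which
#' each requested event is planted at its own codon (third position), so that
#' [build_tables] provably yields known counts. Event types:
#' `syn-poly` (TTT/TTC segregating, outgroup TTT), `nonsyn-poly` (TTT/TTA),
#' `syn-fixed` (ingroup TTC, outgroup TTT), `nonsyn-fixed` (ingroup TTA),
#' `multiallelic` (T/C/A segregating), `unpolarizable` (T/C segregating,
#' outgroup A) and `missing-N` (one ingroup line undetermined). The expected
#' DAF table, divergence summary and exclusion reasons — valid at
#' `depth = n_ingroup` — are returned alongside the alignment, computed by
#' construction rather than by the spectrum pipeline.
#'
#' @param events List of events, each a list with `codon` (1-based index),
#'   `type` (one of the above) and for polymorphic types `derived_count`
#'   (default 1).
#' @param n_ingroup Number of ingroup sequences (default 4).
#' @param n_codons Total codons in the alignment (default: enough for all
#'   events plus 2 invariant codons).
#' @return List with `alignment` (a [cds_alignment]), `expected_daf`,
#'   `expected_div`, `expected_exclusions` (data frame of codon, reason) and
#'   `depth`.
#' @export
make_toy_alignment <- function(events = list(), n_ingroup = 4L,
                               n_codons = NULL) {
  n_codons <- n_codons %||% (length(events) + 2L)
  if (length(events)) {
    codons_used <- vapply(events, function(e) as.integer(e$codon), integer(1))
    if (anyDuplicated(codons_used))
      stop("conflicting events on codon ", codons_used[duplicated(codons_used)][1L])
    if (max(codons_used) > n_codons) stop("event codon index exceeds n_codons")
  }
  ing <- matrix("T", nrow = n_ingroup, ncol = 3L * n_codons)
  outg <- rep("T", 3L * n_codons)

  pn_bins <- integer(n_ingroup - 1L); ps_bins <- integer(n_ingroup - 1L)
  dn <- 0L; ds <- 0L
  excl <- list()
  excluded_codons <- 0L

  for (e in events) {
    type <- match.arg(e$type, TOY_EVENTS)
    ci <- as.integer(e$codon)
    col <- 3L * ci            # third codon position
    dcount <- as.integer(e$derived_count %||% 1L)
    if (type %in% c("syn-poly", "nonsyn-poly", "multiallelic") &&
        (dcount < 1L || dcount > n_ingroup - 1L))
      stop("derived_count must lie in 1..(n_ingroup - 1)")
    switch(type,
      "syn-poly" = {                    # TTT -> TTC, both Phe
        ing[seq_len(dcount), col] <- "C"
        ps_bins[dcount] <- ps_bins[dcount] + 1L
      },
      "nonsyn-poly" = {                 # TTT -> TTA, Phe -> Leu
        ing[seq_len(dcount), col] <- "A"
        pn_bins[dcount] <- pn_bins[dcount] + 1L
      },
      "syn-fixed" = {
        ing[, col] <- "C"
        ds <- ds + 1L
      },
      "nonsyn-fixed" = {
        ing[, col] <- "A"
        dn <- dn + 1L
      },
      "multiallelic" = {
        if (n_ingroup < 3L) stop("multiallelic event needs >= 3 ingroup lines")
        ing[1L, col] <- "C"; ing[2L, col] <- "A"
        excl[[length(excl) + 1L]] <- data.frame(codon = ci - 1L,
                                                reason = "multiallelic")
        excluded_codons <- excluded_codons + 1L
      },
      "unpolarizable" = {               # ingroup T/C, outgroup A
        ing[seq_len(dcount), col] <- "C"
        outg[col] <- "A"
        excl[[length(excl) + 1L]] <- data.frame(codon = ci - 1L,
                                                reason = "unpolarizable")
        excluded_codons <- excluded_codons + 1L
      },
      "missing-N" = {
        ing[1L, col] <- "N"
        excl[[length(excl) + 1L]] <- data.frame(codon = ci - 1L,
                                                reason = "insufficient_depth")
        excluded_codons <- excluded_codons + 1L
      })
  }
  collapse <- function(m) apply(m, 1L, paste, collapse = "")
  ingroup <- collapse(ing)
  names(ingroup) <- sprintf("line%d", seq_len(n_ingroup))
  outgroup <- paste(outg, collapse = "")
  names(outgroup) <- "outgroup"
  retained <- n_codons - excluded_codons
  # every retained codon's ancestral codon is TTT: m_n = 8/3, m_s = 1/3 each
  list(
    alignment = cds_alignment(ingroup, outgroup),
    expected_daf = daf_table(seq_len(n_ingroup - 1L) / n_ingroup,
                             pn_bins, ps_bins, n_sample = n_ingroup),
    expected_div = divergence_summary(dn, ds, m_n = retained * 8 / 3,
                                      m_s = retained * 1 / 3),
    expected_exclusions = if (length(excl)) do.call(rbind, excl)
                          else data.frame(codon = integer(0),
                                          reason = character(0)),
    depth = n_ingroup
  )
}
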