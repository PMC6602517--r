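# Independent oracles and fixture generators used across the suite. These
# re-derive expected values from first principles (combinatorics, textbook
# formulas, per-codon enumeration) and deliberately share no code with the
# implementation paths they check.

# Two-sided Fisher p by direct enumeration of the hypergeometric support with
# choose() arithmetic (no dhyper).
oracle_fisher_p <- function(pn, ps, dn, ds) {
  r1 <- pn + dn; r2 <- ps + ds; c1 <- pn + ps
  if (min(r1, r2, c1, dn + ds) == 0) return(1)
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p <- sum(probs[probs <= probs[ks == pn] * (1 + 1e-7)])
  min(p, 1)
}

# Textbook Cochran-Mantel-Haenszel chi-square (df = 1, no continuity
# correction): X2 = (sum(a - E[a]))^2 / sum(Var[a]).
oracle_cmh_statistic <- function(tabs) {
  a <- sapply(tabs, function(t) t[1, 1])
  r1 <- sapply(tabs, function(t) sum(t[1, ]))
  r2 <- sapply(tabs, function(t) sum(t[2, ]))
  c1 <- sapply(tabs, function(t) sum(t[, 1]))
  c2 <- sapply(tabs, function(t) sum(t[, 2]))
  n <- r1 + r2
  e <- r1 * c1 / n
  v <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  sum(a - e)^2 / sum(v)
}

# Coarse grid search over (a, b, c) with a profiled linear solve for (a, b)
# at each c, refined by Nelder-Mead; returns the best SSE found.
oracle_fit_sse <- function(x, y) {
  best <- NULL
  for (c0 in exp(seq(log(0.01), log(50), length.out = 60))) {
    z <- exp(-c0 * x)
    co <- stats::coef(stats::lm(y ~ z))
    sse <- sum((y - co[1] - co[2] * z)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = c(co[1], co[2], c0), sse = sse)
  }
  obj <- function(p) sum((y - p[1] - p[2] * exp(-max(p[3], 1e-6) * x))^2)
  opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  min(best$sse, opt$value)
}

# Brute-force per-codon spectrum enumerator for full-depth alignments
# (depth = number of ingroup lines, so subsampling is the identity).
# Recomputes classification, polarization and Nei-Gojobori totals directly
# from the genetic code, codon by codon.
oracle_spectrum <- function(aln) {
  code <- Biostrings::GENETIC_CODE
  mat <- do.call(rbind, strsplit(unname(aln$ingroup), ""))
  outg <- strsplit(unname(aln$outgroup), "")[[1]]
  n <- nrow(mat)
  ncod <- length(outg) / 3
  pn <- integer(n - 1); ps <- integer(n - 1); dn <- 0; ds <- 0
  m_n <- 0; m_s <- 0; retained <- 0
  reasons <- character(0)
  acgt <- c("A", "C", "G", "T")
  for (ci in seq_len(ncod)) {
    cols <- lapply(1:3, function(p) mat[, 3 * (ci - 1) + p])
    anc <- outg[(3 * ci - 2):(3 * ci)]
    reason <- NULL
    if (any(sapply(cols, function(cc) any(!cc %in% acgt)))) {
      reason <- "insufficient_depth"
    } else if (any(!anc %in% acgt)) {
      reason <- "unpolarizable"
    } else if (any(sapply(cols, function(cc) length(unique(cc)) > 2))) {
      reason <- "multiallelic"
    } else {
      segregating <- sapply(cols, function(cc) length(unique(cc)) == 2)
      divergent <- sapply(seq_len(3), function(p)
        !segregating[p] && cols[[p]][1] != anc[p])
      if (sum(segregating | divergent) > 1) {
        reason <- "multihit"
      } else if (code[[paste(anc, collapse = "")]] == "*") {
        reason <- "stop"
      } else if (any(segregating) &&
                 !anc[which(segregating)] %in% cols[[which(segregating)]]) {
        reason <- "unpolarizable"
      }
    }
    if (!is.null(reason)) { reasons <- c(reasons, reason); next }
    segregating <- sapply(cols, function(cc) length(unique(cc)) == 2)
    divergent <- sapply(seq_len(3), function(p)
      !segregating[p] && cols[[p]][1] != anc[p])
    anc_codon <- paste(anc, collapse = "")
    syn_change <- function(pos, base) {
      der <- anc; der[pos] <- base
      code[[paste(der, collapse = "")]] == code[[anc_codon]]
    }
    if (any(segregating)) {
      pos <- which(segregating)
      derived <- setdiff(unique(cols[[pos]]), anc[pos])
      count <- sum(cols[[pos]] == derived)
      if (syn_change(pos, derived)) ps[count] <- ps[count] + 1
      else pn[count] <- pn[count] + 1
    } else if (any(divergent)) {
      pos <- which(divergent)
      if (syn_change(pos, cols[[pos]][1])) ds <- ds + 1 else dn <- dn + 1
    }
    for (pos in 1:3) for (base in setdiff(acgt, anc[pos]))
      if (syn_change(pos, base)) m_s <- m_s + 1 / 3 else m_n <- m_n + 1 / 3
    retained <- retained + 1
  }
  list(pn = pn, ps = ps, dn = dn, ds = ds, m_n = m_n, m_s = m_s,
       retained = retained, excluded_reasons = sort(reasons))
}

# Random alignment with planted variation for the oracle-equivalence checks.
random_alignment <- function(n_codons, n_ingroup = 5, seed = 1,
                             p_mut = 0.15, p_n = 0.02) {
  set.seed(seed)
  acgt <- c("A", "C", "G", "T")
  outg <- sample(acgt, 3 * n_codons, replace = TRUE)
  mat <- matrix(rep(outg, each = n_ingroup), nrow = n_ingroup)
  for (j in seq_len(3 * n_codons)) {
    if (runif(1) < p_mut) {
      lines <- sample(n_ingroup, sample(n_ingroup, 1))
      mat[lines, j] <- sample(acgt, 1)
    }
    if (runif(1) < p_n) mat[sample(n_ingroup, 1), j] <- "N"
  }
  ing <- apply(mat, 1, paste, collapse = "")
  names(ing) <- paste0("s", seq_len(n_ingroup))
  og <- paste(outg, collapse = "")
  names(og) <- "out"
  cds_alignment(ing, og)
}

# Random small MK tables and DAF fixtures.
random_table <- function() {
  c(pn = rpois(1, 8), ps = rpois(1, 8), dn = rpois(1, 10), ds = rpois(1, 10))
}

random_daf <- function(n_bins = 8, n_sample = NA, lambda = 4) {
  daf <- sort(sample(seq(0.01, 0.99, by = 0.01), n_bins))
  daf_table(daf, rpois(n_bins, lambda), rpois(n_bins, lambda),
            n_sample = n_sample)
}

random_gene <- function(id, seed) {
  set.seed(seed)
  gene_record(id,
              daf = daf_table(seq_len(19) / 20, rpois(19, 3), rpois(19, 4),
                              n_sample = 20L),
              div = divergence_summary(rpois(1, 15) + 1, rpois(1, 10) + 1,
                                       m_n = 900, m_s = 300),
              metadata = list(chromosome = sample(c("2L", "X"), 1),
                              recombination_rate = round(runif(1, 0, 12), 2)))
}
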