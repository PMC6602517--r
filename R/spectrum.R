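# From aligned coding sequences to MK input: site classification against the
# standard genetic code, subsampling to uniform depth, outgroup polarization,
# and Nei-Gojobori fractional site counting.
#
# Coordinates are 0-based alignment columns internally and in exclusion logs;
# the reading frame starts at column 0 (input must be CDS-trimmed).

VALID_BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Subsample alignment columns to a fixed depth
#'
#' At each alignment column, lines carrying an undetermined base (`N`) or a
#' gap are invalid; if at least `depth` ingroup lines are valid, exactly
#' `depth` of them are drawn without replacement from a seeded per-column
#' stream (so results are independent of column processing order). Columns
#' with fewer valid lines are excluded with reason `"insufficient_depth"`.
#'
#' @param aln A [cds_alignment].
#' @param depth Target number of chromosomes per column (2 <= depth <= number
#'   of ingroup sequences).
#' @param seed Integer seed controlling the subsampling.
#' @return A list with one element per column: either a named integer vector
#'   of base counts summing to `depth`, or `NULL` for excluded columns.
#'   Attribute `"excluded"` holds the 0-based indices of excluded columns.
#' @export
subsample_columns <- function(aln, depth, seed = 1L) {
  stopifnot(inherits(aln, "cds_alignment"))
  n_in <- length(aln$ingroup)
  if (depth > n_in) stop("depth (", depth, ") exceeds ingroup size (", n_in, ")")
  if (depth < 2L) stop("depth must be >= 2")
  mat <- aln_matrix(aln)
  ncols <- ncol(mat)
  out <- vector("list", ncols)
  excluded <- integer(0)
  for (j in seq_len(ncols)) {
    bases <- mat[, j]
    valid <- which(bases %in% VALID_BASES)
    if (length(valid) < depth) {
      excluded <- c(excluded, j - 1L)
      next
    }
    take <- if (length(valid) == depth) valid
            else with_seed(derive_seed(seed, j), valid[sample.int(length(valid), depth)])
    out[[j]] <- table_counts(bases[take])
  }
  attr(out, "excluded") <- excluded
  out
}

table_counts <- function(bases) {
  tab <- table(factor(bases, levels = VALID_BASES))
  counts <- as.integer(tab)
  names(counts) <- VALID_BASES
  counts[counts > 0L]
}

#' Classify a single-nucleotide codon change as neutral or selected
#'
#' A change is neutral (synonymous) when the ancestral and derived codons
#' encode the same amino acid under the standard nuclear genetic code, and
#' selected (nonsynonymous) otherwise, including changes to or from a stop.
#'
#' @param ancestral,derived Three-letter codon strings differing at at most
#'   one position.
#' @return `"neutral"` or `"selected"`; `"invariant"` when the codons are
#'   identical.
#' @examples
#' classify_codon_change("TTT", "TTC")  # both Phe -> neutral
#' classify_codon_change("TTT", "TTA")  # Phe -> Leu -> selected
#' @export
classify_codon_change <- function(ancestral, derived) {
  if (nchar(ancestral) != 3L || nchar(derived) != 3L)
    stop("codons must have length 3")
  ndiff <- sum(strsplit(ancestral, "")[[1L]] != strsplit(derived, "")[[1L]])
  if (ndiff == 0L) return("invariant")
  if (ndiff > 1L) stop("codons differ at more than one position")
  aa1 <- translate_codon(ancestral); aa2 <- translate_codon(derived)
  if (is.na(aa1) || is.na(aa2)) stop("unknown codon")
  if (aa1 == aa2) "neutral" else "selected"
}

#' Resolve overlapping site-class annotations
#'
#' When a nucleotide site belongs to several overlapping transcript frames it
#' may be synonymous in one and nonsynonymous in another; the most selectively
#' constrained class wins (selected over neutral).
#'
#' @param classes Character vector of class proposals, each `"selected"` or
#'   `"neutral"`.
#' @return A single class.
#' @export
resolve_site_class <- function(classes) {
  if (length(classes) < 1L) stop("at least one class proposal is required")
  bad <- setdiff(classes, c("selected", "neutral"))
  if (length(bad)) stop("unknown site class: ", bad[1L])
  if ("selected" %in% classes) "selected" else "neutral"
}

#' Polarize a site by the outgroup base
#'
#' Infers the derived allele of a biallelic or monomorphic ingroup column by
#' comparison with the outgroup. Segregating columns whose outgroup base
#' matches one of the two alleles yield the derived count of the other allele;
#' monomorphic columns differing from the outgroup are fixed differences;
#' columns with more than two alleles, or whose outgroup base is missing or
#' matches neither segregating allele, cannot be polarized.
#'
#' @param counts Named integer vector of ingroup base counts at fixed depth.
#' @param outgroup_base Single outgroup base (`A`/`C`/`G`/`T`), or `N`/`-`
#'   for missing.
#' @return A list with `status` one of `"polymorphic"`, `"fixed_difference"`,
#'   `"monomorphic_conserved"`, `"excluded"`; for polymorphic sites also
#'   `derived_base` and `derived_count`; for exclusions a `reason`
#'   (`"multiallelic"` or `"unpolarizable"`).
#' @examples
#' polarize_site(c(A = 3, T = 1), "A")  # derived count 1
#' polarize_site(c(G = 4), "T")         # fixed difference
#' polarize_site(c(A = 2, T = 2), "C")  # unpolarizable
#' @export
polarize_site <- function(counts, outgroup_base) {
  alleles <- names(counts)[counts > 0L]
  if (length(alleles) > 2L)
    return(list(status = "excluded", reason = "multiallelic"))
  if (!outgroup_base %in% VALID_BASES)
    return(list(status = "excluded", reason = "unpolarizable"))
  if (length(alleles) == 1L) {
    if (alleles == outgroup_base)
      return(list(status = "monomorphic_conserved"))
    return(list(status = "fixed_difference", derived_base = alleles))
  }
  if (!outgroup_base %in% alleles)
    return(list(status = "excluded", reason = "unpolarizable"))
  derived <- setdiff(alleles, outgroup_base)
  list(status = "polymorphic", derived_base = derived,
       derived_count = unname(counts[derived]))
}

#' Nei-Gojobori fractional site totals
#'
#' Counts the numbers of selected (nonsynonymous) and neutral (synonymous)
#' sites in a set of ancestral codons: each codon position contributes
#' (number of its 3 possible single-nucleotide mutations that are
#' synonymous)/3 to `m_s` and the complement to `m_n`, so that
#' `m_n + m_s = 3 *` (number of codons). Mutations creating a stop count as
#' nonsynonymous.
#'
#' @param codons Character vector of ancestral codons (no N or gaps, no stop
#'   codons).
#' @return Named numeric vector `c(m_n = , m_s = )`.
#' @examples
#' count_site_totals("TTT")  # m_n = 8/3, m_s = 1/3
#' count_site_totals("ATG")  # m_n = 3,   m_s = 0
#' @export
count_site_totals <- function(codons) {
  m_n <- 0; m_s <- 0
  for (codon in codons) {
    ng <- codon_site_fractions(codon)
    m_n <- m_n + ng[["m_n"]]; m_s <- m_s + ng[["m_s"]]
  }
  c(m_n = m_n, m_s = m_s)
}

codon_site_fractions <- function(codon) {
  chars <- strsplit(codon, "")[[1L]]
  aa <- translate_codon(codon)
  if (is.na(aa)) stop("unknown codon: ", codon)
  if (aa == "*") stop("stop codon has no site-count definition: ", codon)
  nsyn <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(VALID_BASES, chars[pos])) {
      mut <- chars; mut[pos] <- alt
      if (translate_codon(paste(mut, collapse = "")) == aa) nsyn <- nsyn + 1L
    }
  }
  c(m_n = (9L - nsyn) / 3, m_s = nsyn / 3)
}

#' Build MK input tables from a coding alignment
#'
#' Runs the full spectrum pipeline: per-column subsampling to `depth`
#' ([subsample_columns]), outgroup polarization ([polarize_site]),
#' synonymous/nonsynonymous classification of each single change against the
#' ancestral (outgroup) codon, and Nei-Gojobori site totals over retained
#' codons. A codon is excluded as a whole — with every exclusion logged —
#' when any of its columns lacks depth (`insufficient_depth`), its outgroup
#' codon contains N or a gap (`unpolarizable`), any column carries more than
#' two alleles (`multiallelic`), more than one of its positions is segregating
#' or divergent (`multihit`), a segregating column cannot be polarized
#' (`unpolarizable`), or its ancestral codon is a stop (`stop`).
#'
#' @param aln A [cds_alignment].
#' @param depth Chromosomes sampled per column; default
#'   [default_depth]`(aln)`.
#' @param seed Integer seed for the subsampling streams.
#' @return A list with components `daf` (a [daf_table] with bins at
#'   `i/depth`, `i = 1..depth-1`), `div` (a [divergence_summary] with
#'   Nei-Gojobori `m_n`/`m_s`), `exclusions` (data frame of 0-based `position`,
#'   `codon` and `reason`), and `retained_codons`.
#' @export
build_tables <- function(aln, depth = default_depth(aln), seed = 1L) {
  stopifnot(inherits(aln, "cds_alignment"))
  cols <- subsample_columns(aln, depth, seed)
  out_chars <- strsplit(unname(aln$outgroup), "")[[1L]]
  ncod <- length(out_chars) %/% 3L

  pn_bins <- integer(depth - 1L); ps_bins <- integer(depth - 1L)
  dn <- 0L; ds <- 0L; m_n <- 0; m_s <- 0
  retained <- 0L
  excl_pos <- integer(0); excl_codon <- integer(0); excl_reason <- character(0)

  exclude_codon <- function(ci, reason) {
    idx <- (3L * (ci - 1L)):(3L * ci - 1L)
    excl_pos <<- c(excl_pos, idx)
    excl_codon <<- c(excl_codon, rep(ci - 1L, 3L))
    excl_reason <<- c(excl_reason, rep(reason, 3L))
  }

  for (ci in seq_len(ncod)) {
    jdx <- (3L * ci - 2L):(3L * ci)          # 1-based column indices
    counts3 <- cols[jdx]
    if (any(vapply(counts3, is.null, logical(1)))) {
      exclude_codon(ci, "insufficient_depth"); next
    }
    anc <- out_chars[jdx]
    if (any(!anc %in% VALID_BASES)) {
      exclude_codon(ci, "unpolarizable"); next
    }
    n_alleles <- vapply(counts3, length, integer(1))
    if (any(n_alleles > 2L)) {
      exclude_codon(ci, "multiallelic"); next
    }
    mono_base <- vapply(counts3, function(cc)
      if (length(cc) == 1L) names(cc) else NA_character_, character(1))
    variable <- n_alleles == 2L | (!is.na(mono_base) & mono_base != anc)
    if (sum(variable) > 1L) {
      exclude_codon(ci, "multihit"); next
    }
    anc_codon <- paste(anc, collapse = "")
    if (translate_codon(anc_codon) == "*") {
      exclude_codon(ci, "stop"); next
    }
    if (any(variable)) {
      k <- which(variable)
      pol <- polarize_site(counts3[[k]], anc[k])
      if (pol$status == "excluded") {
        exclude_codon(ci, pol$reason); next
      }
      der <- anc; der[k] <- pol$derived_base
      cls <- classify_codon_change(anc_codon, paste(der, collapse = ""))
      if (pol$status == "polymorphic") {
        i <- pol$derived_count
        if (cls == "selected") pn_bins[i] <- pn_bins[i] + 1L
        else ps_bins[i] <- ps_bins[i] + 1L
      } else {                                # fixed_difference
        if (cls == "selected") dn <- dn + 1L else ds <- ds + 1L
      }
    }
    ng <- codon_site_fractions(anc_codon)
    m_n <- m_n + ng[["m_n"]]; m_s <- m_s + ng[["m_s"]]
    retained <- retained + 1L
  }

  if (retained == 0L) stop("empty_after_filters: no codon survives the filters")
  list(
    daf = daf_table(seq_len(depth - 1L) / depth, pn_bins, ps_bins,
                    n_sample = depth),
    div = divergence_summary(dn, ds, m_n = m_n, m_s = m_s),
    exclusions = data.frame(position = excl_pos, codon = excl_codon,
                            reason = excl_reason, stringsAsFactors = FALSE),
    retained_codons = retained
  )
}

#' Default subsampling depth for an alignment
#'
#' The largest depth n such that at least 90% of alignment columns have n or
#' more ingroup lines with a determined base, maximizing the number of
#' informative sites while keeping most columns analyzable.
#'
#' @param aln A [cds_alignment].
#' @param coverage Minimum fraction of columns that must reach the depth.
#' @return An integer depth (at least 2).
#' @export
default_depth <- function(aln, coverage = 0.9) {
  stopifnot(inherits(aln, "cds_alignment"))
  mat <- aln_matrix(aln)
  valid_per_col <- colSums(matrix(mat %in% VALID_BASES, nrow = nrow(mat)))
  for (n in rev(seq(2L, length(aln$ingroup))))
    if (mean(valid_per_col >= n) >= coverage) return(n)
  2L
}
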