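#' Construct a derived allele frequency (DAF) table
#'
#' A DAF table holds the unfolded site frequency spectrum of two site classes:
#' a putatively selected class (typically nonsynonymous coding sites, counts
#' `pn`) and a putatively neutral class (typically synonymous sites, counts
#' `ps`), binned by the frequency of the derived allele. Frequencies are
#' strictly inside (0, 1): monomorphic and fixed classes belong in the
#' divergence summary, not here.
#'
#' @param daf Numeric vector of derived allele frequencies, each in the open
#'   interval (0, 1). Stored sorted increasing; must contain no duplicates.
#' @param pn,ps Non-negative integer counts of selected-class and
#'   neutral-class segregating variants per frequency bin.
#' @param n_sample Number of chromosomes sampled (the spectrum depth), or
#'   `NA` when unknown. When given, frequencies are typically `i / n_sample`.
#' @return An object of class `daf_table`: a data frame with columns `daf`,
#'   `pn`, `ps` and attribute `n_sample`.
#' @examples
#' daf_table(c(0.25, 0.5, 0.75), pn = c(3, 1, 0), ps = c(5, 2, 4), n_sample = 4)
#' @export
daf_table <- function(daf, pn, ps, n_sample = NA_integer_) {
  if (length(daf) < 1L) stop("a DAF table needs at least one frequency bin")
  if (length(pn) != length(daf) || length(ps) != length(daf))
    stop("daf, pn and ps must have equal length")
  if (!is.numeric(daf) || any(!is.finite(daf)))
    stop("daf values must be finite numbers")
  if (any(daf <= 0) || any(daf >= 1))
    stop("daf values must lie strictly inside (0, 1); ",
         "fixed differences belong in the divergence summary")
  if (!is_count(pn) || !is_count(ps))
    stop("pn and ps must be non-negative integer counts")
  o <- order(daf)
  daf <- daf[o]; pn <- round(pn[o]); ps <- round(ps[o])
  if (any(diff(daf) <= 0)) stop("daf values must be distinct")
  if (!is.na(n_sample)) {
    n_sample <- as.integer(n_sample)
    if (n_sample < 2L) stop("n_sample must be >= 2")
  }
  out <- data.frame(daf = daf, pn = as.integer(pn), ps = as.integer(ps))
  attr(out, "n_sample") <- n_sample
  class(out) <- c("daf_table", "data.frame")
  out
}

#' @export
print.daf_table <- function(x, ...) {
  n <- attr(x, "n_sample")
  cat(sprintf("DAF table: %d bins, n_sample = %s, sum Pn = %d, sum Ps = %d\n",
              nrow(x), ifelse(is.na(n), "unknown", n), sum(x$pn), sum(x$ps)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Construct a divergence summary
#'
#' Counts of fixed differences to the outgroup in the selected (`dn`) and
#' neutral (`ds`) site classes, together with the numbers of analyzed sites in
#' each class (`m_n`, `m_s`). Site totals may be `NA` (unknown); they are
#' required only for the selection-regime fractions of the extended MK test.
#'
#' @param dn,ds Non-negative counts of selected- and neutral-class fixed
#'   differences.
#' @param m_n,m_s Numbers of selected and neutral sites analyzed (may be
#'   fractional under Nei-Gojobori counting), or `NA` when unknown.
#' @return An object of class `divergence_summary`.
#' @examples
#' divergence_summary(dn = 20, ds = 10, m_n = 300, m_s = 100)
#' @export
divergence_summary <- function(dn, ds, m_n = NA_real_, m_s = NA_real_) {
  if (!is_count(dn) || !is_count(ds))
    stop("dn and ds must be non-negative integer counts")
  for (m in list(m_n, m_s))
    if (!is.na(m) && (!is.numeric(m) || m < 0))
      stop("m_n and m_s must be non-negative or NA")
  if (!is.na(m_n) && m_n > 0 && dn > m_n) stop("dn cannot exceed m_n")
  if (!is.na(m_s) && m_s > 0 && ds > m_s) stop("ds cannot exceed m_s")
  structure(list(dn = as.numeric(dn), ds = as.numeric(ds),
                 m_n = as.numeric(m_n), m_s = as.numeric(m_s)),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Divergence: Dn = %g, Ds = %g, m_n = %s, m_s = %s\n",
              x$dn, x$ds,
              ifelse(is.na(x$m_n), "unknown", format(x$m_n)),
              ifelse(is.na(x$m_s), "unknown", format(x$m_s))))
  invisible(x)
}

#' Construct a gene record
#'
#' Bundles one gene's DAF table, divergence summary and free-form metadata
#' (conventionally `chromosome` and `recombination_rate` in cM/Mb) under a
#' unique gene identifier, for cohort-level analysis.
#'
#' @param gene_id Non-empty gene identifier (symbol or database ID).
#' @param daf A [daf_table].
#' @param div A [divergence_summary].
#' @param metadata Named list of metadata values.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, daf, div, metadata = list()) {
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id))
    stop("gene_id must be a non-empty string")
  stopifnot(inherits(daf, "daf_table"), inherits(div, "divergence_summary"))
  if (!is.list(metadata)) stop("metadata must be a list")
  structure(list(gene_id = gene_id, daf = daf, div = div, metadata = metadata),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("Gene %s: %d DAF bins (Pn = %d, Ps = %d), Dn = %g, Ds = %g\n",
              x$gene_id, nrow(x$daf), sum(x$daf$pn), sum(x$daf$ps),
              x$div$dn, x$div$ds))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a coding-sequence alignment with outgroup
#'
#' An in-frame alignment of two or more same-species coding sequences
#' (the ingroup, used for polymorphism) plus exactly one outgroup orthologue
#' (used for divergence and ancestral-state inference). All sequences must
#' have equal length divisible by 3; the alphabet is A, C, G, T, N, `-`
#' (gap, treated as missing).
#'
#' @param ingroup Named character vector of >= 2 aligned ingroup sequences.
#' @param outgroup Named character vector of length 1: the outgroup sequence.
#' @return An object of class `cds_alignment`.
#' @export
cds_alignment <- function(ingroup, outgroup) {
  if (length(ingroup) < 2L) stop("at least two ingroup sequences are required")
  if (length(outgroup) != 1L) stop("exactly one outgroup sequence is required")
  if (is.null(names(ingroup)) || any(!nzchar(names(ingroup))) ||
      is.null(names(outgroup)) || !nzchar(names(outgroup)))
    stop("all sequences must be named")
  ids <- c(names(ingroup), names(outgroup))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(c(ingroup, outgroup))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("all sequences must have equal length (aligned input required)")
  if (lens[1L] %% 3L != 0L)
    stop("alignment length must be divisible by 3 (CDS-trimmed input required)")
  if (lens[1L] == 0L) stop("empty alignment")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in sequence ", ids[bad][1L],
         " (allowed: A, C, G, T, N, -)")
  structure(list(ingroup = seqs[seq_along(ingroup)],
                 outgroup = seqs[length(seqs)]),
            class = "cds_alignment")
}

#' @export
print.cds_alignment <- function(x, ...) {
  cat(sprintf("CDS alignment: %d ingroup sequences + outgroup '%s', %d bp (%d codons)\n",
              length(x$ingroup), names(x$outgroup), nchar(x$outgroup),
              nchar(x$outgroup) %/% 3L))
  invisible(x)
}

# Character matrix (rows = sequences) of the ingroup; internal.
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$ingroup), "", fixed = TRUE))
}
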