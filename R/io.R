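# Readers and writers for the external representations the package touches:
# tab-delimited DAF and divergence files, aligned multi-FASTA, JSON-lines gene
# datasets and a long-format TSV importer. All text I/O is UTF-8 with "." as
# the decimal separator.

default_daf_dialect <- c(daf = "daf", pn = "Pn", ps = "Ps")

#' Read a tab-delimited DAF table
#'
#' The default dialect expects a header `daf<TAB>Pn<TAB>Ps`; other column
#' names can be mapped via `dialect`. Rows with zero counts are preserved and
#' the table is normalized to ascending frequency order.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Named character vector mapping the canonical names
#'   `daf`, `pn`, `ps` to the column names used in the file.
#' @param n_sample Sample depth (number of chromosomes). When `NA`, it is
#'   inferred as the smallest q <= 512 such that every frequency is i/q for
#'   integer i; left `NA` if no such q exists.
#' @return A [daf_table].
#' @seealso [write_daf_table()]
#' @export
read_daf_table <- function(path, dialect = default_daf_dialect,
                           n_sample = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- dialect[c("daf", "pn", "ps")]
  if (anyNA(need)) stop("dialect must map 'daf', 'pn' and 'ps'")
  miss <- setdiff(unname(need), names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) | !nzchar(trimws(tab[[col]])))
    if (length(bad))
      stop(sprintf("malformed %s value at line %d of %s", what, bad[1L] + 1L, path))
    x
  }
  daf <- num(need[["daf"]], "daf")
  pn <- num(need[["pn"]], "Pn")
  ps <- num(need[["ps"]], "Ps")
  if (any(daf >= 1))
    stop("daf value >= 1 at line ", which(daf >= 1)[1L] + 1L, " of ", path,
         ": fixed variants are divergence, not polymorphism")
  if (any(daf <= 0))
    stop("daf value <= 0 at line ", which(daf <= 0)[1L] + 1L, " of ", path)
  if (is.na(n_sample)) n_sample <- infer_n_sample(daf)
  daf_table(daf, pn, ps, n_sample = n_sample)
}

infer_n_sample <- function(daf) {
  for (q in 2:512)
    if (all(abs(daf * q - round(daf * q)) < 1e-6)) return(q)
  NA_integer_
}

#' Write a DAF table to a tab-delimited file
#'
#' @param x A [daf_table].
#' @param path Output path; header `daf<TAB>Pn<TAB>Ps`.
#' @return `path`, invisibly.
#' @export
write_daf_table <- function(x, path) {
  stopifnot(inherits(x, "daf_table"))
  out <- data.frame(daf = format(x$daf, digits = 15, trim = TRUE),
                    Pn = x$pn, Ps = x$ps)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a divergence-counts file
#'
#' One-row tab-delimited file with header `mn<TAB>Dn<TAB>ms<TAB>Ds`.
#' The site-total columns `mn`/`ms` may be absent or empty; they are then
#' recorded as unknown (`NA`), which only precludes the extended-MKT
#' selection-regime fractions.
#'
#' @param path Path to the file.
#' @return A [divergence_summary].
#' @export
read_divergence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(tab) <- tolower(names(tab))
  if (nrow(tab) != 1L) stop("divergence file must contain exactly one data row")
  for (col in c("dn", "ds"))
    if (!col %in% names(tab)) stop("missing column '", col, "' in ", path)
  getcol <- function(col) {
    if (!col %in% names(tab)) return(NA_real_)
    v <- suppressWarnings(as.numeric(tab[[col]][1L]))
    v
  }
  dn <- getcol("dn"); ds <- getcol("ds")
  if (is.na(dn) || is.na(ds)) stop("Dn and Ds must be numeric in ", path)
  if (dn < 0 || ds < 0) stop("negative divergence count in ", path)
  divergence_summary(dn = dn, ds = ds, m_n = getcol("mn"), m_s = getcol("ms"))
}

#' Write a divergence summary
#'
#' @param x A [divergence_summary].
#' @param path Output path; header `mn<TAB>Dn<TAB>ms<TAB>Ds`, one data row.
#'   Unknown site totals are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_divergence <- function(x, path) {
  stopifnot(inherits(x, "divergence_summary"))
  fmt <- function(v) if (is.na(v)) "" else format(v, digits = 15, trim = TRUE)
  lines <- c("mn\tDn\tms\tDs",
             paste(fmt(x$m_n), fmt(x$dn), fmt(x$m_s), fmt(x$ds), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an aligned multi-FASTA of coding sequences with an outgroup
#'
#' Expects >= 2 same-species (ingroup) sequences plus one outgroup orthologue
#' named `outgroup_id`, all aligned to equal length divisible by 3.
#' Record ids are the first whitespace-delimited token of each FASTA header.
#'
#' @param path FASTA file path.
#' @param outgroup_id Record id of the outgroup sequence.
#' @return A [cds_alignment].
#' @export
read_fasta_alignment <- function(path, outgroup_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record id in ", path, ": ", ids[duplicated(ids)][1L])
  if (!outgroup_id %in% ids)
    stop("outgroup id '", outgroup_id, "' not found in ", path)
  if (length(set) < 3L)
    stop("need at least two ingroup sequences plus the outgroup")
  seqs <- as.character(set)
  names(seqs) <- ids
  cds_alignment(ingroup = seqs[ids != outgroup_id],
                outgroup = seqs[outgroup_id])
}

#' Write an alignment as multi-FASTA
#'
#' @param aln A [cds_alignment].
#' @param path Output path. The outgroup record is written last.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "cds_alignment"))
  seqs <- c(aln$ingroup, aln$outgroup)
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
             path, useBytes = TRUE)
  invisible(path)
}

gene_to_json <- function(g) {
  jsonlite::toJSON(list(
    gene_id = g$gene_id,
    n_sample = attr(g$daf, "n_sample"),
    daf = g$daf$daf, pn = g$daf$pn, ps = g$daf$ps,
    dn = g$div$dn, ds = g$div$ds, m_n = g$div$m_n, m_s = g$div$m_s,
    metadata = g$metadata
  ), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

#' Write a gene dataset as JSON lines
#'
#' One JSON object per line per gene, with the DAF bins inlined; the format
#' round-trips through [read_gene_dataset()] exactly.
#'
#' @param genes List of [gene_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_dataset <- function(genes, path) {
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_record")))
  writeLines(vapply(genes, function(g) as.character(gene_to_json(g)),
                    character(1)), path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene dataset from JSON lines
#'
#' @param path Path to a JSON-lines file as written by [write_gene_dataset()].
#' @return List of [gene_record] objects.
#' @export
read_gene_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  genes <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop("malformed JSON at line ", i, " of ", path, ": ",
                           conditionMessage(e)))
    md <- as.list(rec$metadata %||% list())
    if (!is.null(md$recombination_rate))
      md$recombination_rate <- as.numeric(md$recombination_rate)
    gene_record(
      gene_id = rec$gene_id,
      daf = daf_table(rec$daf, rec$pn, rec$ps,
                      n_sample = rec$n_sample %||% NA_integer_),
      div = divergence_summary(rec$dn, rec$ds,
                               m_n = rec$m_n %||% NA_real_,
                               m_s = rec$m_s %||% NA_real_),
      metadata = md)
  })
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicated gene_id in ", path, ": ", ids[duplicated(ids)][1L])
  genes
}

#' Import a gene dataset from long-format TSV
#'
#' Polymorphism rows `(gene_id, daf, pn, ps)` — one row per gene and
#' frequency bin — with divergence supplied in a companion TSV
#' `(gene_id, dn, ds[, m_n, m_s])` and optional extra metadata columns
#' (e.g. `chromosome`, `recombination_rate`) on the divergence table.
#'
#' @param daf_path TSV with columns `gene_id`, `daf`, `pn`, `ps`.
#' @param div_path TSV with columns `gene_id`, `dn`, `ds` and optional
#'   `m_n`, `m_s` plus metadata columns.
#' @return List of [gene_record] objects.
#' @export
read_gene_dataset_tsv <- function(daf_path, div_path) {
  poly <- utils::read.delim(daf_path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  div <- utils::read.delim(div_path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  for (col in c("gene_id", "daf", "pn", "ps"))
    if (!col %in% names(poly)) stop("missing column '", col, "' in ", daf_path)
  for (col in c("gene_id", "dn", "ds"))
    if (!col %in% names(div)) stop("missing column '", col, "' in ", div_path)
  if (anyDuplicated(div$gene_id))
    stop("duplicated gene_id in ", div_path, ": ",
         div$gene_id[duplicated(div$gene_id)][1L])
  meta_cols <- setdiff(names(div), c("gene_id", "dn", "ds", "m_n", "m_s"))
  lapply(div$gene_id, function(id) {
    rows <- poly[poly$gene_id == id, , drop = FALSE]
    if (!nrow(rows)) stop("no DAF rows for gene ", id)
    drow <- div[div$gene_id == id, , drop = FALSE]
    md <- as.list(drow[1L, meta_cols, drop = FALSE])
    if (!is.null(md$recombination_rate))
      md$recombination_rate <- as.numeric(md$recombination_rate)
    gene_record(
      gene_id = id,
      daf = daf_table(rows$daf, rows$pn, rows$ps,
                      n_sample = infer_n_sample(rows$daf)),
      div = divergence_summary(drow$dn[1L], drow$ds[1L],
                               m_n = if ("m_n" %in% names(drow)) drow$m_n[1L] else NA_real_,
                               m_s = if ("m_s" %in% names(drow)) drow$m_s[1L] else NA_real_),
      metadata = md)
  })
}
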