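# Result report: canonical JSON (deterministic serialization) and a minimal
# static HTML view with the same sections in the same order — input
# parameters, descriptive statistics, the standard MKT table, the selected
# tests, optional cohort comparisons and warnings. The report is a view: it
# serializes results computed elsewhere and never recomputes a number.

result_to_list <- function(res) {
  if (inherits(res, "mkt")) {
    out <- list(method = res$method,
                alpha = res$alpha,
                p_value = res$p_value,
                table = as.list(res$table),
                cutoff = res$cutoff,
                notes = as.list(res$notes))
    if (!is.null(res$fractions)) out$fractions <- as.list(res$fractions)
    if (!is.null(res$fit))
      out$fit <- list(model = res$fit$model, a = res$fit$a, b = res$fit$b,
                      c = res$fit$c %||% NULL,
                      alpha_asymptote = res$fit$alpha_asymptote,
                      x_interval = res$fit$x_interval,
                      converged = res$fit$converged)
    if (!is.null(res$ci_low)) { out$ci_low <- res$ci_low; out$ci_high <- res$ci_high }
    if (!is.null(res$trajectory))
      out$trajectory <- list(x = res$trajectory$x, alpha = res$trajectory$alpha)
    return(out)
  }
  if (inherits(res, "cmh_result"))
    return(list(variant = res$variant, statistic = res$statistic,
                df = res$df, p_value = res$p_value, k_strata = res$k_strata))
  if (inherits(res, "mkt_boot"))
    return(list(method = res$method, mean = res$mean, sd = res$sd,
                ci_low = res$ci_low, ci_high = res$ci_high,
                n_reps = res$n_reps, n_failed = res$n_failed,
                sample_size = res$sample_size, seed = res$seed))
  if (inherits(res, "mkt_comparison"))
    return(list(labels = res$labels,
                group_a = result_to_list(res$boot_a),
                group_b = result_to_list(res$boot_b),
                difference = res$difference,
                method = res$method, n_reps = res$n_reps, seed = res$seed))
  res
}

descriptive_stats <- function(daf, div) {
  list(sum_pn = sum(daf$pn), sum_ps = sum(daf$ps),
       n_bins = nrow(daf), n_sample = attr(daf, "n_sample"),
       dn = div$dn, ds = div$ds, m_n = div$m_n, m_s = div$m_s,
       spectrum = list(daf = daf$daf, pn = daf$pn, ps = daf$ps))
}

#' Render an analysis report
#'
#' Assembles the canonical report from module outputs and serializes it as
#' JSON (always) and a minimal static HTML page (optional). Sections appear
#' in a fixed order — parameters, descriptive statistics, standard MKT,
#' selected tests, cohort comparisons, warnings — and serialization is
#' deterministic: the same inputs produce byte-identical output.
#'
#' @param daf,div The analyzed [daf_table] and [divergence_summary]
#'   (descriptive statistics are taken from them).
#' @param results Named list of test results (`mkt`, `cmh_result`,
#'   `mkt_boot` or `mkt_comparison` objects). A result named `standard`
#'   fills the standard-MKT section; the rest go under `tests`.
#' @param parameters Named list of input parameters to echo (files, cutoffs,
#'   seeds).
#' @param warnings Character vector of warnings to include.
#' @param json_path,html_path Output file paths (`NULL` to skip writing).
#' @return The report list, invisibly; written files as side effects.
#' @export
render_report <- function(daf, div, results, parameters = list(),
                          warnings = character(0), json_path = NULL,
                          html_path = NULL) {
  if (!length(results)) stop("at least one result is required")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list")
  report <- list(
    parameters = parameters,
    descriptive_statistics = descriptive_stats(daf, div),
    standard_mkt = if ("standard" %in% names(results))
      result_to_list(results[["standard"]]) else NULL,
    tests = lapply(results[setdiff(names(results), "standard")],
                   result_to_list),
    warnings = as.list(warnings),
    version = as.character(utils::packageVersion("mktools"))
  )
  report <- report[!vapply(report, is.null, logical(1))]
  if (!is.null(json_path)) {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null", pretty = TRUE)
    writeLines(json, json_path, useBytes = TRUE)
  }
  if (!is.null(html_path)) writeLines(report_html(report), html_path,
                                      useBytes = TRUE)
  invisible(report)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_kv_table <- function(lst) {
  flat <- lst[!vapply(lst, is.list, logical(1))]
  rows <- vapply(names(flat), function(k)
    sprintf("<tr><td>%s</td><td>%s</td></tr>", html_escape(k),
            html_escape(paste(format(flat[[k]], digits = 10), collapse = ", "))),
    character(1))
  paste0("<table border='1'>", paste(rows, collapse = ""), "</table>")
}

report_html <- function(report) {
  sec <- function(title, body) sprintf("<h2>%s</h2>\n%s", title, body)
  parts <- c(
    "<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    "<title>MK test report</title></head><body>",
    "<h1>McDonald-Kreitman test report</h1>",
    sec("Input parameters", html_kv_table(report$parameters)),
    sec("Descriptive statistics",
        html_kv_table(report$descriptive_statistics)))
  if (!is.null(report$standard_mkt))
    parts <- c(parts, sec("Standard MKT", html_kv_table(report$standard_mkt)))
  for (nm in names(report$tests))
    parts <- c(parts, sec(paste("Test:", nm), html_kv_table(report$tests[[nm]])))
  if (length(report$warnings))
    parts <- c(parts, sec("Warnings", paste0(
      "<ul>", paste0("<li>", html_escape(unlist(report$warnings)), "</li>",
                     collapse = ""), "</ul>")))
  c(parts, sprintf("<p>mktools %s</p>", report$version), "</body></html>")
}
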