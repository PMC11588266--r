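#' Render a simulation report as CSV or markdown
#'
#' Rows are ordered by (scenario, n, beta, gamma, method); cells with
#' `|ARebias| >= 0.05` are flagged (a logical `flagged` column in CSV,
#' bold in markdown).  Displayed numbers are rounded to 3 decimals; the
#' CSV keeps full precision so that a round trip through
#' [utils::read.csv()] reproduces the report.
#'
#' @param report A [run_grid()] report (or equivalent data frame).
#' @param format `"csv"` or `"markdown"`.
#' @param path Optional output file; the document is also returned.
#' @return Invisibly for CSV (the data frame written), a character
#'   vector of markdown lines otherwise.
#' @export
render_results_table <- function(report, format = c("csv", "markdown"),
                                 path = NULL) {
  format <- match.arg(format)
  need <- c("scenario", "n", "beta", "gamma", "method",
            "arebias", "arebias_se", "mse")
  stopifnot(is.data.frame(report), all(need %in% names(report)))
  if (nrow(report) == 0L || !any(!is.na(report$method))) {
    stop("empty report", call. = FALSE)
  }
  tab <- as.data.frame(report)[union(need, names(report))]
  tab <- tab[order(tab$scenario, tab$n, tab$beta, tab$gamma, tab$method), ,
             drop = FALSE]
  tab$flagged <- !is.na(tab$arebias) & abs(tab$arebias) >= 0.05

  if (format == "csv") {
    if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  fmt3 <- function(v) ifelse(is.na(v), "", sprintf("%.3f", v))
  ar <- sprintf("%s (%s)", fmt3(tab$arebias), fmt3(tab$arebias_se))
  ar[tab$flagged] <- paste0("**", ar[tab$flagged], "**")
  lines <- c(
    "| scenario | n | beta | gamma | method | ARebias (SE) | MSE |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %d | %d | %g | %g | %s | %s | %s |",
            tab$scenario, tab$n, tab$beta, tab$gamma, tab$method,
            ar, fmt3(tab$mse))
  )
  if (!is.null(path)) writeLines(lines, path)
  lines
}

#' Render an effect-estimate table
#'
#' Formats odds ratios as `OR (low-high)` with 2 decimals and marks an
#' estimate significant (`*`) when its interval strictly excludes 1.
#'
#' @param estimates Data frame with columns `method`, `or_point`,
#'   `ci_low`, `ci_high` (and optionally `term`, `ci_method`).
#' @param path Optional output CSV path.
#' @return Data frame with the formatted column `or_ci` and logical
#'   `significant`.
#' @export
render_effect_table <- function(estimates, path = NULL) {
  need <- c("method", "or_point", "ci_low", "ci_high")
  stopifnot(is.data.frame(estimates), all(need %in% names(estimates)))
  out <- as.data.frame(estimates)
  out$significant <- out$ci_low > 1 | out$ci_high < 1   # strict exclusion
  out$or_ci <- sprintf("%.2f (%.2f-%.2f)%s",
                       out$or_point, out$ci_low, out$ci_high,
                       ifelse(out$significant, "*", ""))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Write a JSON run manifest next to an output file
#'
#' Records the configuration, seed, package version and failure counts
#' of a run for reproducibility audits.
#'
#' @param out_path The output file the manifest describes; the manifest
#'   is written as `<out_path>.manifest.json`.
#' @param config Named list of configuration values.
#' @param seed Integer seed of the run.
#' @param n_failures Failure count (default 0).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(out_path, config = list(), seed = NA_integer_,
                               n_failures = 0L) {
  manifest <- list(
    output = basename(out_path),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("ordadjust")),
    seed = seed,
    n_failures = n_failures,
    config = config
  )
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
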