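# JSON serialization of TII estimates, with provenance, for exchange
# between CLI runs (compute -> regress) and downstream tooling.

#' Write and read TII estimates as JSON
#'
#' The JSON file records, per taxon, the full replicate list, median,
#' quartiles and outlier indices, alongside provenance (metric, iteration
#' count, seed, and any caller-supplied fields), so downstream steps can
#' reuse the estimates without recomputation.
#'
#' @param x a `taxon_influence` fit or list of `tii_estimate` objects.
#' @param path output path.
#' @param provenance named list of extra provenance fields to record.
#' @return `write_estimates_json` returns `path` invisibly;
#'   `read_estimates_json` returns a named list of `tii_estimate` objects.
#' @export
write_estimates_json <- function(x, path, provenance = list()) {
  if (inherits(x, "taxon_influence")) {
    provenance <- c(provenance,
                    list(metric = x$spec$metric, n_iter = x$n_iter,
                         seed = x$seed))
    x <- x$estimates
  }
  stopifnot(all(vapply(x, inherits, TRUE, "tii_estimate")))
  payload <- list(
    provenance = provenance,
    estimates = lapply(x, function(e) {
      list(taxon = e$taxon, replicates = e$replicates, median = e$median,
           q1 = e$q1, q3 = e$q3, outliers = as.integer(e$outliers),
           n_iter = e$n_iter, metric = e$metric)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_estimates_json
#' @export
read_estimates_json <- function(path) {
  if (!file.exists(path)) stop("estimates file not found: ", path,
                               call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  est <- lapply(payload$estimates, function(e) {
    tii_estimate(e$taxon, as.numeric(e$replicates),
                 metric = if (is.null(e$metric)) NA else e$metric)
  })
  names(est) <- vapply(est, `[[`, "", "taxon")
  est
}
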