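#' Read chamber decay series from CSV
#'
#' Expects a header line with columns `time_s`, `concentration`,
#' `compound`; one file may carry several compounds, each becoming one
#' [decay_series()].
#'
#' @param path CSV file path.
#' @return A named list of [decay_series()], one per compound, in order
#'   of first appearance.
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "concentration", "compound")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' is missing required columns: ",
         paste(miss, collapse = ", "), " (header required)")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$concentration))
  if (length(bad))
    stop("non-numeric or missing values in '", path, "' at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- lapply(split(df, factor(df$compound, levels = unique(df$compound))),
                function(d) decay_series(d$compound[1], d$time_s,
                                         d$concentration))
  out
}

#' Write chamber decay series to CSV
#'
#' Inverse of [read_decay_csv()]: full double precision is preserved so a
#' write/read round trip is lossless.
#'
#' @param series A [decay_series()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(series, path) {
  if (inherits(series, "decay_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(time_s = s$times, concentration = s$concentrations,
               compound = s$compound_id, stringsAsFactors = FALSE)))
  .write_full_precision(df, path)
}

#' Write fate-model time trends to CSV
#'
#' Columns `time_d, ibp_w, ibap_w, ibap_g`, full double precision.
#'
#' @param tr A data frame from [trends()], [simulate_ode()] or
#'   [generate_fate_observations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trends_csv <- function(tr, path) {
  need <- c("time_d", "ibp_w", "ibap_w", "ibap_g")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trends are missing columns: ", paste(miss, collapse = ", "))
  .write_full_precision(tr[need], path)
}

#' Read fate-model time trends from CSV
#'
#' @param path CSV path written by [write_trends_csv()].
#' @return A data frame with columns `time_d, ibp_w, ibap_w, ibap_g`.
#' @export
read_trends_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("time_d", "ibp_w", "ibap_w", "ibap_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' is missing required columns: ",
         paste(miss, collapse = ", "), " (header required)")
  df[need]
}

# write.csv at 17 significant digits so doubles round-trip exactly
.write_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON report for a relative-rate determination
#'
#' Assembles the regression summary and the derived second-order rate
#' constant into one machine-diffable record.
#'
#' @param fit A `relative_rate_fit`.
#' @param ref A [reference_compound()].
#' @param path Optional path; if given, the report is written as JSON.
#' @return The report as a named list (invisibly if written to `path`).
#' @export
relrate_report <- function(fit, ref, path = NULL) {
  k <- ratio_to_rate_constant(fit, ref)
  rep <- list(reference = ref$name,
              slope = fit$slope, sigma_slope = fit$sigma_slope,
              intercept = fit$intercept, r2 = fit$r_squared,
              k_value = k$value, k_sigma = k$sigma, units = k$units)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
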