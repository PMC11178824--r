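# Dataset container and delimited-text round trip.  Every dataset knows the
# simulation conditions that produced (or would reproduce) it, so objective
# functions and recovery tests can be driven from the data alone.

#' Construct a dataset object
#'
#' @param type one of `"bands_timecourse"`, `"occupancy_timecourse"`,
#'   `"initial_rate"`, `"dose_response"`, `"distribution"`.
#' @param data replicate-level data frame.
#' @param summary per-point summary data frame (means and SDs across
#'   replicates) used by objective functions.
#' @param meta list of metadata: simulation conditions (`variant`,
#'   `rate_mode`, `y0`, `enzymes`, `times` or grid), the generating seed and
#'   noise model, and (for synthetic data) the ground truth.
#' @return object of class `phos_dataset`.
#' @export
phos_dataset <- function(type, data, summary, meta = list()) {
  type <- match.arg(type, c("bands_timecourse", "occupancy_timecourse",
                            "initial_rate", "dose_response", "distribution"))
  structure(list(type = type, data = data, summary = summary, meta = meta),
            class = "phos_dataset")
}

#' @export
print.phos_dataset <- function(x, ...) {
  cat("phos_dataset [", x$type, "]: ", nrow(x$data), " rows",
      if (!is.null(x$meta$name)) paste0(" (", x$meta$name, ")"), "\n",
      sep = "")
  invisible(x)
}

.fraction_cols <- c("f0", "f1", "f2", "f3", "f4")

#' Write a dataset to delimited text with a JSON metadata sidecar
#'
#' Writes `<path>.csv` (replicate-level data), `<path>_summary.csv` and
#' `<path>.json` (type + metadata).  Values round-trip within 1e-12.
#'
#' @param ds `phos_dataset`.
#' @param path file path prefix (no extension).
#' @export
write_phos_dataset <- function(ds, path) {
  fmt <- function(df) {
    out <- df
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    }
    out
  }
  utils::write.csv(fmt(ds$data), paste0(path, ".csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(ds$summary), paste0(path, "_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- ds$meta
  meta$.type <- ds$type
  # named numeric vectors must become JSON objects, not bare arrays
  for (nm in c("y0", "enzymes", "enzymes_base")) {
    if (!is.null(meta[[nm]])) meta[[nm]] <- as.list(meta[[nm]])
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_phos_dataset()]
#'
#' Schema violations (missing fraction columns, negative or >1 fractions)
#' are rejected with the offending row number; unknown extra columns are
#' preserved with a warning.
#'
#' @param path file path prefix used at write time.
#' @return `phos_dataset`.
#' @export
read_phos_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  type <- meta$.type
  meta$.type <- NULL
  for (nm in c("y0", "enzymes", "enzymes_base")) {
    if (!is.null(meta[[nm]])) meta[[nm]] <- unlist(meta[[nm]])
  }
  data <- utils::read.csv(paste0(path, ".csv"))
  summary <- utils::read.csv(paste0(path, "_summary.csv"))
  expected <- switch(type,
    bands_timecourse = c("time_s", "replicate", .fraction_cols),
    occupancy_timecourse = c("time_s", "replicate",
                             paste0("occ_", PHOS_SITES)),
    initial_rate = c("substrate_molar", "replicate", "rate"),
    dose_response = c("conc_molar", "replicate", .fraction_cols),
    distribution = c("replicate", .fraction_cols)
  )
  missing_cols <- setdiff(expected, names(data))
  if (length(missing_cols)) {
    stop("dataset ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(data), expected)
  if (length(extra)) {
    warning("dataset ", path, " carries unknown columns (kept): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  fr <- intersect(.fraction_cols, names(data))
  for (cc in fr) {
    bad <- which(data[[cc]] < 0 | data[[cc]] > 1)
    if (length(bad)) {
      stop("dataset ", path, ": fraction column ", cc,
           " out of [0,1] at row ", bad[1], call. = FALSE)
    }
  }
  phos_dataset(type, data, summary, meta)
}

#' Write a time course in the state-vector CSV schema
#'
#' Columns `time_s, c_0P, c_a, c_ab, c_abg, c_d, c_ad, c_abd, c_abgd`
#' (plus `c_aprime` for the structural-transition variant), mol/L.
#'
#' @param tc `phos_timecourse`.
#' @param path output CSV path.
#' @export
write_timecourse_csv <- function(tc, path) {
  df <- data.frame(time_s = tc$times, tc$states, check.names = FALSE)
  names(df) <- c("time_s", paste0("c_", colnames(tc$states)))
  for (j in seq_along(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
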