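#' Read and write MVAR model descriptors
#'
#' The descriptor is JSON with fields `n`, `p`, `coeffs` (a list of `p`
#' row-major `n` x `n` arrays) and `noise_cov`. Matrices round-trip to
#' full double precision.
#'
#' @param model An [mvar_model()].
#' @param path File path.
#' @return `write_mvar_model()` returns `path` invisibly;
#'   `read_mvar_model()` returns an [mvar_model()].
#' @export
write_mvar_model <- function(model, path) {
  stopifnot(inherits(model, "mvar_model"))
  jsonlite::write_json(
    list(n = model$n, p = model$p,
         coeffs = lapply(model$coeffs, identity),
         noise_cov = model$noise_cov),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mvar_model
#' @export
read_mvar_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- x$coeffs
  if (is.array(coeffs) && length(dim(coeffs)) == 3) {
    coeffs <- lapply(seq_len(dim(coeffs)[1]), function(k) coeffs[k, , ])
  } else if (is.matrix(coeffs)) {
    coeffs <- list(coeffs)
  }
  mvar_model(coeffs, as.matrix(x$noise_cov))
}

#' Write multi-trial time series as delimited text
#'
#' One file per trial, rows = time points, columns = elements, with a
#' header row `e1..en`. Tab-delimited by default.
#'
#' @param data A [phi_ts()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `prefix_trialNNN.tsv`.
#' @param delim Field delimiter, tab or comma.
#' @return Character vector of the written paths, invisibly.
#' @export
write_time_series <- function(data, dir, prefix = "trial", delim = "\t") {
  stopifnot(inherits(data, "phi_ts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (delim == ",") "csv" else "tsv"
  paths <- character(data$trials)
  for (tr in seq_len(data$trials)) {
    df <- as.data.frame(data$values[[tr]])
    names(df) <- paste0("e", seq_len(data$n))
    paths[tr] <- file.path(dir, sprintf("%s_%03d.%s", prefix, tr, ext))
    readr::write_delim(df, paths[tr], delim = delim)
  }
  invisible(paths)
}

#' Read multi-trial time series from delimited text files
#'
#' @param paths Character vector of file paths (one per trial) or a single
#'   glob pattern such as `"trials/trial_*.tsv"`. The delimiter (tab or
#'   comma) and the presence of a header row are sniffed from the first
#'   line.
#' @return A [phi_ts()] object.
#' @export
read_time_series <- function(paths) {
  if (length(paths) == 1 && grepl("[*?]", paths))
    paths <- Sys.glob(paths)
  if (length(paths) == 0) stop("no time-series files found", call. = FALSE)
  values <- lapply(paths, function(p) {
    first <- readLines(p, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
    has_header <- grepl("[A-Za-z]", first)
    m <- as.matrix(utils::read.table(p, sep = delim, header = has_header))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  })
  phi_ts(values)
}

#' Serialize an integrated-information result
#'
#' JSON with the measure label, lag, value, the MIB as two 1-based index
#' lists, the full per-bipartition record table, and provenance.
#'
#' @param result A `phi_result`.
#' @param path Output path for JSON (`write_phi_result()`) or CSV of the
#'   record table (`write_phi_records_csv()`).
#' @return `path`, invisibly.
#' @export
write_phi_result <- function(result, path) {
  stopifnot(inherits(result, "phi_result"))
  jsonlite::write_json(
    list(measure = result$measure, tau = result$tau, value = result$value,
         mib = list(part1 = result$mib$part1, part2 = result$mib$part2),
         records = result$records,
         provenance = result$provenance),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phi_result
#' @export
write_phi_records_csv <- function(result, path) {
  stopifnot(inherits(result, "phi_result"))
  readr::write_csv(result$records, path)
  invisible(path)
}
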