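#' Read and write mixture datasets in the upload dialect
#'
#' The tabular upload dialect has one data point per row with a header row and
#' columns `SMILES1` (or `MOL1`, a path to an SDF/MOL file), `MOLAR_FRACTION`,
#' `SMILES2` (or `MOLID2`/`MOL2`), `PROPERTY`, `VALUE`, `UNIT`, `SOURCE`, and
#' optionally `NAME2`. Rows are canonicalized on read (majority component
#' first, complement-to-1 fractions), so a file row with fraction 0.30 yields
#' a stored record with `x1 = 0.70` and the components interchanged.
#' Row-level parse failures are collected and reported with row numbers.
#'
#' `write_mixture_dataset()` writes the canonical records back out in the same
#' dialect (csv), so `read(write(d))` reproduces `d` up to floating-point
#' formatting. Reading xlsx requires the \pkg{readxl} package; no xlsx writer
#' is bundled, so writing is csv-only.
#'
#' @param path file path.
#' @param format `"csv"` or `"xlsx"`; default guessed from the file extension.
#' @inheritParams canonicalize_rows
#' @return `read_mixture_dataset()` returns a [mixture_dataset()];
#'   `write_mixture_dataset()` returns `path` invisibly.
#' @export
read_mixture_dataset <- function(path, format = c("auto", "csv", "xlsx"),
                                 canonicalizer = canonicalizer_identity(),
                                 endpoint_kind = c("regression", "classification"),
                                 concentration_dependent = TRUE) {
  format <- match.arg(format)
  endpoint_kind <- match.arg(endpoint_kind)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character"),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_mixqspr("readxl is required to read xlsx files", "mixqspr_config_error")
      }
      as.data.frame(readxl::read_excel(path, col_types = "text"),
                    stringsAsFactors = FALSE)
    }
  )
  mandatory <- c("MOLAR_FRACTION", "VALUE")
  miss <- setdiff(mandatory, names(raw))
  if (!any(c("SMILES1", "MOL1") %in% names(raw))) miss <- c("SMILES1", miss)
  if (length(miss)) {
    stop_mixqspr(paste("missing mandatory column(s):", paste(miss, collapse = ", ")),
                 "mixqspr_schema_error")
  }
  canonicalize_rows(raw, canonicalizer = canonicalizer,
                    endpoint_kind = endpoint_kind,
                    concentration_dependent = concentration_dependent)
}

#' @rdname read_mixture_dataset
#' @param dataset a [mixture_dataset()].
#' @export
write_mixture_dataset <- function(dataset, path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  if (format == "xlsx") {
    stop_mixqspr("no xlsx writer is available; write csv instead", "mixqspr_config_error")
  }
  out <- data.frame(
    SMILES1 = dataset$comp1,
    MOLAR_FRACTION = format(dataset$x1, digits = 15),
    SMILES2 = ifelse(is.na(dataset$comp2), "", dataset$comp2),
    PROPERTY = dataset$property,
    VALUE = if (is.numeric(dataset$value)) format(dataset$value, digits = 15)
            else as.character(dataset$value),
    UNIT = ifelse(is.na(dataset$unit), "", dataset$unit),
    SOURCE = ifelse(is.na(dataset$source), "", dataset$source),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
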