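#' Read a univariate sample from a text or CSV file
#'
#' Accepted formats: plain text with one numeric value per line (`#` starts
#' a comment), or CSV with a single numeric column, with or without a header
#' row. Format is chosen by file extension when `format = "auto"`.
#'
#' @param path file path.
#' @param format `"auto"`, `"txt"` or `"csv"`.
#' @param column column name or index for multi-column CSV files.
#' @return Numeric vector in file order.
#' @export
read_sample <- function(path, format = c("auto", "txt", "csv"),
                        column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  if (format == "txt") {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    keep <- nzchar(lines)
    if (!any(keep)) stop("no data in ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(lines[keep]))
    if (anyNA(vals)) {
      bad <- which(keep)[which(is.na(vals))[1]]
      stop("non-numeric value at line ", bad, " of ", path, call. = FALSE)
    }
    return(vals)
  }
  df <- utils::read.csv(path, header = TRUE)
  # re-read headerless if the header row was itself numeric (read.csv
  # mangles a numeric header cell to e.g. "X0.7")
  hdr <- sub("^X", "", names(df)[1])
  if (ncol(df) == 1 && !is.na(suppressWarnings(as.numeric(hdr))))
    df <- utils::read.csv(path, header = FALSE)
  if (!is.null(column)) {
    vals <- df[[column]]
    if (is.null(vals)) stop("no column '", column, "' in ", path,
                            call. = FALSE)
  } else if (ncol(df) == 1) {
    vals <- df[[1]]
  } else {
    stop(path, " has ", ncol(df),
         " columns; select one with the 'column' argument", call. = FALSE)
  }
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals)))))[1]
    stop("non-numeric value at data row ", bad, " of ", path, call. = FALSE)
  }
  if (!length(vals)) stop("no data in ", path, call. = FALSE)
  as.numeric(vals)
}

#' Write a reproducible Lehmann-alternative fixture
#'
#' Draws a sample with [rlehmann()] and writes it as a plain-text file (one
#' value per line, full precision) together with a JSON sidecar
#' (`<path>.json`) recording the generator truth: model name and parameters,
#' `theta`, `n` and `seed`. Regenerating with the same arguments is
#' byte-identical.
#'
#' @param path output file path.
#' @param model a [gof_model()].
#' @param theta positive Lehmann parameter of the generating truth.
#' @param n sample size.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(path, model, theta, n, seed) {
  stopifnot(inherits(model, "gof_model"))
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is required for a reproducible fixture", call. = FALSE)
  x <- rlehmann(n, model, theta, seed = seed)
  writeLines(formatC(x, format = "g", digits = 17), path)
  meta <- list(model = model$name,
               params = as.list(model$params),
               theta = theta, n = as.integer(n), seed = as.integer(seed))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
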