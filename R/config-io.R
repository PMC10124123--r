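#' Write a flat key/value configuration document
#'
#' One `key: value` pair per line; vector values are comma-separated.  The
#' format is plain text and readable without this package.  Numeric scalars
#' survive a round trip exactly (written with full precision).
#'
#' @param config named list of atomic scalars or vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), length(names(config)) == length(config),
            all(nzchar(names(config))))
  fmt1 <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17, scientific = TRUE,
                                    trim = TRUE), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", fmt1(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value configuration document
#'
#' Inverse of [write_run_config()]: values that parse as numbers are returned
#' numeric, comma-separated values as vectors, everything else as character.
#'
#' @param path file written by [write_run_config()] (or by hand).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexpr("^[^:]+", ln))
    if (!length(m)) next
    key <- trimws(m)
    val <- trimws(sub("^[^:]+:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) && !anyNA(num)) num else parts
  }
  out
}
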