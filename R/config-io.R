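#' Read a flat key-value configuration file
#'
#' The package's configuration dialect is deliberately minimal: one
#' \code{key = value} pair per line, \code{#} comments, blank lines ignored.
#' Keys are dot-separated; values are returned as character and coerced by
#' callers.
#'
#' @param path file to read.
#' @return named character vector.
#' @seealso [writeFlatConfig()], [readPhantomLayout()]
#' @export
readFlatConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  key <- trimws(sub("=.*$", "", lines))
  val <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(key))
    stop("duplicate config key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  stats::setNames(val, key)
}

#' Write a flat key-value configuration file
#'
#' @param values named vector (coerced to character).
#' @param path file to write.
#' @param header optional comment line written at the top.
#' @return \code{path}, invisibly.
#' @export
writeFlatConfig <- function(values, path, header = NULL) {
  stopifnot(!is.null(names(values)), all(nzchar(names(values))))
  lines <- paste(names(values), "=", as.character(values))
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}
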