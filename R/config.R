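#' Read a flat key-value configuration file
#'
#' Parses files of `key = value` lines (one per line; `#` starts a
#' comment). Values that parse as numbers become numeric; everything else
#' stays character. Units follow the package conventions: lengths in nm,
#' molar masses in kg/mol, densities in kg/m^3, concentrations in mg/L,
#' rates in SI.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_kv_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  num <- suppressWarnings(as.numeric(vals))
  out <- as.list(ifelse(is.na(num), vals, num))
  out <- lapply(seq_along(out), function(i) {
    if (is.na(num[i])) vals[i] else num[i]
  })
  names(out) <- keys
  out
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of scalars.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kv_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, character(1))), path)
  invisible(path)
}
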