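# Delimited-text spectrum files: '#'-prefixed metadata header with the full
# configuration echo, then field / derivative / absorption columns written
# at full double precision so a paired read reproduces the values exactly.

.flatten_meta <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (inherits(v, "spin_system")) {
      out <- c(out,
               .flatten_meta(list(S = v$S,
                                  g = paste(v$g, collapse = " ")),
                             paste0(key, "")),
               vapply(v$terms, function(t)
                 sprintf("%s.B_%d_%d: %.17g", key, t$k, t$q, t$B), ""))
    } else if (inherits(v, "epr_experiment")) {
      vv <- v[!vapply(v, is.null, TRUE)]
      out <- c(out, .flatten_meta(vv, key))
    } else if (is.list(v)) {
      out <- c(out, .flatten_meta(v, key))
    } else if (length(v) > 0) {
      out <- c(out, sprintf("%s: %s", key,
                            paste(format(v, digits = 17), collapse = " ")))
    }
  }
  out
}

#' Write and read spectra as delimited text
#'
#' `write_spectrum()` stores an `epr_spectrum` as plain text: header lines
#' prefixed `#` carrying the configuration echo as `key: value` pairs,
#' followed by three whitespace-delimited columns `field_gauss`,
#' `derivative_intensity`, `absorption_intensity` at full double precision
#' (17 significant digits), so that `read_spectrum()` restores the numeric
#' traces exactly.
#'
#' @param x an `epr_spectrum`.
#' @param path file path.
#' @return `write_spectrum()`: `path`, invisibly.  `read_spectrum()`: an
#'   `epr_spectrum` whose metadata holds the parsed header lines.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "epr_spectrum"))
  hdr <- c("# giantspin spectrum v1",
           paste0("# ", .flatten_meta(x$metadata[
             setdiff(names(x$metadata), "warnings")])),
           "# columns: field_gauss derivative_intensity absorption_intensity")
  body <- sprintf("%.17g %.17g %.17g", x$field_G, x$derivative,
                  x$absorption)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^# ?", "", lines[is_hdr])
  kv <- grep(": ", hdr, value = TRUE, fixed = TRUE)
  meta <- as.list(sub("^[^:]*: ", "", kv))
  names(meta) <- sub(":.*$", "", kv)
  dat <- read.table(text = lines[!is_hdr], col.names =
                      c("field_G", "derivative", "absorption"))
  structure(list(field_G = dat$field_G, absorption = dat$absorption,
                 derivative = dat$derivative,
                 metadata = c(meta, list(source_file = path))),
            class = "epr_spectrum")
}
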