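## Touchstone 1.x (.s1p) and CSV reflection-spectrum I/O.

.ts_units <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)

#' Read a one-port reflection spectrum
#'
#' Supports Touchstone 1.x `.s1p` (option line such as `# GHz S RI R 50`,
#' with `RI`, `MA` and `DB` data formats) and CSV files with columns
#' `f_Hz` (or `f_GHz`) plus either `re_s11`/`im_s11` or `s11_db`
#' (`re_gamma`/`im_gamma` and `mag_db` are accepted aliases). Frequencies
#' must be strictly increasing.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"touchstone"` or `"csv"`.
#' @return A [reflection_spectrum].
#' @export
read_spectrum <- function(path, dialect = c("auto", "touchstone", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.s1p$", path, ignore.case = TRUE))
      "touchstone" else "csv"
  if (dialect == "touchstone") .read_s1p(path) else .read_spectrum_csv(path)
}

.read_s1p <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unit <- "GHZ"; fmt <- "MA"
  opt_seen <- FALSE
  fr <- c(); v1 <- c(); v2 <- c()
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (opt_seen) next  # per Touchstone 1.x, later option lines ignored
      toks <- toupper(strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]])
      toks <- toks[nzchar(toks)]
      j <- 1L
      while (j <= length(toks)) {
        tk <- toks[j]
        if (tk %in% names(.ts_units)) unit <- tk
        else if (tk %in% c("RI", "MA", "DB")) fmt <- tk
        else if (tk == "S") NULL
        else if (tk == "R") j <- j + 1L  # skip reference resistance value
        else stop(sprintf("%s:%d: malformed Touchstone option line token '%s'",
                          path, i, tk))
        j <- j + 1L
      }
      opt_seen <- TRUE
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:],]+")[[1]]))
    if (length(vals) != 3L || any(is.na(vals)))
      stop(sprintf("%s:%d: expected 3 numeric fields, got '%s'",
                   path, i, lines[i]))
    fr <- c(fr, vals[1]); v1 <- c(v1, vals[2]); v2 <- c(v2, vals[3])
  }
  if (!length(fr)) stop(path, ": no data lines found")
  f <- fr * .ts_units[[unit]]
  if (is.unsorted(f, strictly = TRUE))
    stop(path, ": frequencies are not strictly increasing")
  s <- switch(fmt,
    RI = complex(real = v1, imaginary = v2),
    MA = v1 * exp(1i * v2 * pi / 180),
    DB = 10^(v1 / 20) * exp(1i * v2 * pi / 180))
  reflection_spectrum(f, s11 = s,
                      meta = list(path = path, dialect = "touchstone",
                                  unit = unit, format = fmt))
}

.read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  nms <- tolower(names(d))
  fcol <- match(TRUE, nms %in% c("f_hz", "frequency", "frequency_hz"))
  fghz <- match(TRUE, nms %in% c("f_ghz", "frequency_ghz"))
  if (!is.na(fcol)) f <- d[[fcol]]
  else if (!is.na(fghz)) f <- d[[fghz]] * 1e9
  else stop(path, ": no frequency column (f_Hz or f_GHz) found")
  if (is.unsorted(f, strictly = TRUE))
    stop(path, ": frequencies are not strictly increasing")
  re <- match(TRUE, nms %in% c("re_s11", "re_gamma", "re"))
  im <- match(TRUE, nms %in% c("im_s11", "im_gamma", "im"))
  db <- match(TRUE, nms %in% c("s11_db", "mag_db"))
  if (!is.na(re) && !is.na(im)) {
    reflection_spectrum(f, s11 = complex(real = d[[re]], imaginary = d[[im]]),
                        meta = list(path = path, dialect = "csv"))
  } else if (!is.na(db)) {
    reflection_spectrum(f, s11_db = d[[db]],
                        meta = list(path = path, dialect = "csv"))
  } else {
    stop(path, ": need re/im columns or an s11_db column")
  }
}

#' Write a one-port reflection spectrum
#'
#' @param spectrum A [reflection_spectrum].
#' @param path Output file path.
#' @param dialect `"touchstone"` or `"csv"`.
#' @param format Touchstone data format: `"RI"`, `"MA"` or `"DB"`.
#' @param f_unit Touchstone frequency unit: `"GHz"`, `"MHz"`, `"kHz"`, `"Hz"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           dialect = c("touchstone", "csv"),
                           format = c("RI", "MA", "DB"), f_unit = "GHz") {
  stopifnot(inherits(spectrum, "reflection_spectrum"))
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  num <- function(x) sprintf("%.17g", x)
  if (dialect == "touchstone") {
    if (anyNA(spectrum$s11))
      stop("spectrum has no complex S11 values; cannot write Touchstone")
    un <- match.arg(toupper(f_unit), names(.ts_units))
    fq <- spectrum$frequency / .ts_units[[un]]
    s <- spectrum$s11
    ab <- switch(format,
      RI = cbind(Re(s), Im(s)),
      MA = cbind(Mod(s), Arg(s) * 180 / pi),
      DB = cbind(20 * log10(Mod(s)), Arg(s) * 180 / pi))
    hdr <- sprintf("# %s S %s R 50",
                   c(HZ = "Hz", KHZ = "kHz", MHZ = "MHz", GHZ = "GHz")[[un]],
                   format)
    writeLines(c("! skinwave reflection spectrum", hdr,
                 paste(num(fq), num(ab[, 1]), num(ab[, 2]))), path)
  } else {
    s <- spectrum$s11
    d <- data.frame(f_Hz = num(spectrum$frequency),
                    re_s11 = num(Re(s)), im_s11 = num(Im(s)),
                    s11_db = num(spectrum$s11_db))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
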