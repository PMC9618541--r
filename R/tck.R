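#' Streamline tractogram
#'
#' An ordered collection of streamlines, each an n x 3 matrix of vertices in
#' world millimetres (n >= 2), plus free-form header metadata. This is the
#' in-memory form of a TCK file.
#'
#' @param streamlines list of numeric matrices, each n x 3 with n >= 2 and
#'   all coordinates finite.
#' @param header named list of header key/values (e.g. `count`).
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list(), header = list()) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("each streamline must be an n x 3 matrix")
    if (nrow(s) < 2L) stop("each streamline needs >= 2 vertices")
    if (!all(is.finite(s))) stop("streamline contains non-finite coordinates")
    dimnames(s) <- NULL
    s
  })
  header$count <- length(streamlines)
  structure(list(streamlines = streamlines, header = header),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat("<tractogram> ", n, " streamline", if (n != 1) "s", "\n", sep = "")
  if (n > 0) {
    nv <- vapply(x$streamlines, nrow, integer(1))
    cat("  vertices per streamline: ", min(nv), "-", max(nv),
        " (total ", sum(nv), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Read a TCK tractogram
#'
#' Parses the MRtrix track file format: a text header opening with the magic
#' line `mrtrix tracks` and closing with `END`, followed at the declared
#' byte offset by float triplets -- vertices in world mm, one
#' `(NaN,NaN,NaN)` separator after each streamline and an `(Inf,Inf,Inf)`
#' terminator. Float32/float64 in either endianness are accepted.
#'
#' A missing terminator is a corrupt-file error; a `count` field that
#' disagrees with the actual number of streamlines raises a warning and the
#' actual count is used.
#'
#' @param path path to a `.tck` file.
#' @return a [tractogram()].
#' @export
read_tck <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header is ASCII up to "END\n"
  end_at <- find_tck_end(bytes)
  hdr_txt <- rawToChar(bytes[seq_len(end_at)])
  lines <- strsplit(hdr_txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0 || trimws(lines[1]) != "mrtrix tracks") {
    stop("not a TCK file (missing 'mrtrix tracks' magic line): ", path)
  }
  header <- list()
  for (ln in lines[-1]) {
    if (trimws(ln) == "END") break
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) == 2) header[[trimws(kv[1])]] <- trimws(kv[2])
  }
  datatype <- header$datatype %||% "Float32LE"
  fmt <- switch(datatype,
    Float32LE = list(size = 4, endian = "little"),
    Float32BE = list(size = 4, endian = "big"),
    Float64LE = list(size = 8, endian = "little"),
    Float64BE = list(size = 8, endian = "big"),
    stop("unsupported TCK datatype: ", datatype)
  )
  offset <- as.numeric(sub("^\\.\\s+", "", header$file %||% ""))
  if (!is.finite(offset)) stop("TCK header has no valid 'file' offset: ", path)

  body <- bytes[(offset + 1):length(bytes)]
  vals <- readBin(body, "double", n = length(body) / fmt$size,
                  size = fmt$size, endian = fmt$endian)
  if (length(vals) %% 3 != 0) vals <- vals[seq_len(length(vals) %/% 3 * 3)]
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(matrix(is.nan(m), ncol = 3)) == 3
  is_inf <- is.infinite(m[, 1]) & !is_nan
  term <- which(is_inf)
  if (length(term) == 0) stop("corrupt TCK file (no Inf terminator): ", path)
  term <- term[1]
  streamlines <- list()
  start <- 1L
  for (i in seq_len(term)) {
    if (i == term || is_nan[i]) {
      if (i > start) streamlines[[length(streamlines) + 1L]] <-
        m[start:(i - 1), , drop = FALSE]
      start <- i + 1L
    }
  }
  declared <- suppressWarnings(as.integer(header$count))
  if (length(declared) == 1 && !is.na(declared) &&
      declared != length(streamlines)) {
    warning("TCK 'count' field (", declared, ") != actual streamline count (",
            length(streamlines), "); using actual count")
  }
  header$count <- NULL
  tractogram(streamlines, header)
}

find_tck_end <- function(bytes) {
  # locate "END\n" scanning only the ASCII prefix
  pat <- charToRaw("END\n")
  limit <- min(length(bytes) - 3L, 65536L)
  for (i in seq_len(limit)) {
    if (bytes[i] == pat[1] && bytes[i + 1] == pat[2] &&
        bytes[i + 2] == pat[3] && bytes[i + 3] == pat[4]) {
      return(i + 3L)
    }
  }
  stop("not a TCK file (header not terminated by END)")
}

#' Write a TCK tractogram
#'
#' Writes little-endian float32 (`Float32LE`) track data readable by
#' [read_tck()] and by MRtrix tools: NaN-triplet separators after each
#' streamline, a single Inf-triplet terminator, and a correct `count`
#' header field.
#'
#' @param tractogram a [tractogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tractogram, path) {
  stopifnot(inherits(tractogram, "tractogram"))
  sl <- tractogram$streamlines
  extra <- tractogram$header
  extra$count <- NULL; extra$datatype <- NULL; extra$file <- NULL
  fixed <- c("mrtrix tracks",
             paste0("count: ", length(sl)),
             "datatype: Float32LE",
             vapply(names(extra), function(k) paste0(k, ": ", extra[[k]]),
                    character(1)))
  # the offset field's own width feeds back into the offset; iterate to fix
  offset <- 0
  repeat {
    hdr <- paste0(paste(c(fixed, paste0("file: . ", offset), "END"),
                        collapse = "\n"), "\n")
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  body <- unlist(lapply(sl, function(s) c(t(s), rep(NaN, 3))))
  body <- c(body, rep(Inf, 3))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(hdr, con, eos = NULL)
  writeBin(as.double(body), con, size = 4, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
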