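#' Read a flow-cytometry standard (FCS) file
#'
#' Compact reader for FCS 2.0 / 3.0 / 3.1 list-mode files covering the
#' common layouts emitted by bench cytometers: `$DATATYPE` `F` (32-bit
#' float), `D` (64-bit float) or `I` (16/32-bit unsigned integers),
#' little- or big-endian `$BYTEORD`, list mode (`$MODE` `L`).  Only the
#' first dataset of a multi-dataset file is read.
#'
#' @param path Path to the FCS file.
#' @return A list with `data` (data frame, one column per channel named
#'   by `$PnN`), `n_events`, `text` (the raw TEXT-segment keywords).
#' @seealso [ingest_fcs()] to extract one channel as an event table.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!grepl("^FCS[23]\\.[01]$", version)) {
    stop("not a supported FCS file (header '", version, "')", call. = FALSE)
  }
  off <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(header, a, b))))
    if (is.na(v)) 0 else v
  }
  text_start <- off(11, 18)
  text_end <- off(19, 26)
  data_start <- off(27, 34)
  data_end <- off(35, 42)
  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1, length(parts), by = 2)])
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), toupper(keys))
  need <- function(k) {
    if (is.null(kw[[k]])) stop("FCS file lacks required keyword ", k,
                               call. = FALSE)
    kw[[k]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (grepl("^1", byteord)) "little" else "big"
  if (data_start == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(need(paste0("$P", i, "B")))
  }, 0L)
  chans <- vapply(seq_len(n_par), function(i) {
    v <- kw[[paste0("$P", i, "N")]]
    if (is.null(v)) paste0("P", i) else v
  }, "")
  seek(con, data_start)
  n_values <- n_par * n_tot
  mat <- if (dtype == "F") {
    if (any(bits != 32L)) stop("$DATATYPE F requires $PnB = 32", call. = FALSE)
    readBin(con, "numeric", n = n_values, size = 4, endian = endian)
  } else if (dtype == "D") {
    readBin(con, "numeric", n = n_values, size = 8, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(16L, 32L)) {
      stop("only uniform 16- or 32-bit integer data supported", call. = FALSE)
    }
    readBin(con, "integer", n = n_values, size = bits[1] / 8,
            signed = bits[1] < 32L, endian = endian)
  } else {
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  }
  if (length(mat) < n_values) {
    stop("truncated DATA segment: expected ", n_values, " values, read ",
         length(mat), call. = FALSE)
  }
  m <- matrix(mat, nrow = n_tot, ncol = n_par, byrow = TRUE,
              dimnames = list(NULL, chans))
  list(data = as.data.frame(m), n_events = n_tot, text = kw)
}

#' Extract one fluorescence channel from an FCS file as an event table
#'
#' @param path Path to the FCS file.
#' @param channel Channel name (`$PnN`), e.g. `"FL1-H"` for GFP.
#' @param time Time label to attach to the acquisition (e.g. `"18h"`).
#' @return Data frame with columns `time`, `intensity` (one row per
#'   event, acquisition order preserved).
#' @export
ingest_fcs <- function(path, channel, time = "0h") {
  fcs <- read_fcs(path)
  if (!channel %in% names(fcs$data)) {
    stop("channel '", channel, "' not present; available channels: ",
         paste(names(fcs$data), collapse = ", "), call. = FALSE)
  }
  data.frame(time = time, intensity = as.numeric(fcs$data[[channel]]),
             stringsAsFactors = FALSE)
}
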