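#' Construct a FlowSample
#'
#' The in-memory representation of one list-mode acquisition: channel
#' metadata, an event-by-channel intensity matrix, an optional spillover
#' matrix, and a transform state that moves strictly
#' raw -> compensated -> transformed.
#'
#' @param events numeric matrix (events x channels).
#' @param channels data.frame with columns \code{index}, \code{short_name},
#'   \code{marker}, \code{range}. If missing, built from the matrix column
#'   names.
#' @param spillover optional square spillover matrix with detector dimnames
#'   (rows = source detector, columns = receiving detector, unit diagonal).
#' @param transform_state one of \code{"raw"}, \code{"compensated"},
#'   \code{"transformed"}.
#' @param metadata named list of keywords (e.g. \code{sample_id}, \code{age},
#'   \code{leukocyte_conc}).
#' @return An object of class \code{flow_sample}.
#' @export
flow_sample <- function(events, channels = NULL, spillover = NULL,
                        transform_state = "raw", metadata = list()) {
  if (!is.matrix(events)) events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.null(channels)) {
    nm <- colnames(events) %||% paste0("P", seq_len(ncol(events)))
    channels <- data.frame(index = seq_len(ncol(events)), short_name = nm,
                           marker = "", range = 262144,
                           stringsAsFactors = FALSE)
  }
  if (ncol(events) != nrow(channels))
    stop_validation("events has %d columns but %d channels described",
                    ncol(events), nrow(channels))
  if (anyDuplicated(channels$short_name))
    stop_validation("channel short names must be unique")
  if (any(!nzchar(channels$short_name)))
    stop_validation("channel short names must be non-empty")
  if (!is.null(spillover)) {
    spillover <- as.matrix(spillover)
    if (nrow(spillover) != ncol(spillover))
      stop_validation("spillover matrix must be square")
    if (any(abs(diag(spillover) - 1) > 1e-9))
      stop_validation("spillover matrix must have a unit diagonal")
  }
  transform_state <- match.arg(transform_state, c("raw", "compensated", "transformed"))
  colnames(events) <- channels$short_name
  structure(list(events = events, channels = channels, spillover = spillover,
                 transform_state = transform_state, metadata = metadata),
            class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("<flow_sample> %d events x %d channels [%s]\n",
              nrow(x$events), nrow(x$channels), x$transform_state))
  mk <- x$channels$marker
  cat("  channels:", paste(ifelse(nzchar(mk), mk, x$channels$short_name), collapse = " "), "\n")
  if (!is.null(x$spillover)) cat("  spillover: ", nrow(x$spillover), "x", ncol(x$spillover), "\n")
  invisible(x)
}

#' Event matrix keyed by marker name
#'
#' Returns the event matrix with columns renamed to the stain label where one
#' is present (detector name otherwise), which is how all gating-level code
#' addresses channels.
#'
#' @param sample a \code{flow_sample}.
#' @return numeric matrix.
#' @export
marker_matrix <- function(sample) {
  m <- sample$events
  mk <- sample$channels$marker
  colnames(m) <- ifelse(nzchar(mk), mk, sample$channels$short_name)
  m
}

fcs_header_offsets <- function(con) {
  version <- rawToChar(readBin(con, "raw", 6))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_format("unsupported FCS version '%s' (only 3.0/3.1)", version)
  readBin(con, "raw", 4)  # four spaces
  off <- sapply(1:6, function(i) {
    s <- trimws(rawToChar(readBin(con, "raw", 8)))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  })
  if (anyNA(off)) stop_format("malformed HEADER segment: non-numeric offsets")
  list(version = version, text = off[1:2], data = off[3:4], analysis = off[5:6])
}

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  if (endsWith(body, delim)) body <- substr(body, 1, nchar(body) - 1)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # The standard forbids empty values, so an empty part signals an escaped
  # (doubled) delimiter inside the surrounding field: merge it back.
  fields <- character(0)
  i <- 1; n <- length(parts)
  while (i <= n) {
    cur <- parts[i]; i <- i + 1
    while (i <= n && parts[i] == "") {
      nxt <- if (i + 1 <= n) parts[i + 1] else ""
      cur <- paste0(cur, delim, nxt)
      i <- i + 2
    }
    fields <- c(fields, cur)
  }
  if (length(fields) %% 2 == 1)
    stop_format("malformed TEXT segment: odd keyword/value count near '%s'",
                utils::tail(fields, 1))
  keys <- toupper(trimws(fields[seq(1, length(fields), 2)]))
  vals <- fields[seq(2, length(fields), 2)]
  stats::setNames(as.list(vals), keys)
}

parse_spillover_keyword <- function(value) {
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  n <- suppressWarnings(as.integer(parts[1]))
  if (is.na(n) || length(parts) < 1 + n + n * n)
    stop_format("malformed $SPILLOVER keyword")
  nms <- trimws(parts[2:(1 + n)])
  vals <- as.numeric(parts[(2 + n):(1 + n + n * n)])
  m <- matrix(vals, nrow = n, byrow = TRUE, dimnames = list(nms, nms))
  m
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Parses the HEADER and TEXT segments, reads the DATA segment for
#' \code{$DATATYPE} F (float32), D (double) or I (unsigned integers of
#' \code{$PnB} bits), honouring \code{$BYTEORD}, and returns a
#' \code{\link{flow_sample}} in the \code{raw} transform state. A
#' \code{$SPILLOVER} (or \code{SPILL}/\code{$COMP}) keyword, when present, is
#' parsed into the sample's spillover matrix.
#'
#' @param path path to an FCS file.
#' @return A \code{flow_sample}.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- fcs_header_offsets(con)
  seek(con, hdr$text[1])
  raw_text <- readBin(con, "raw", hdr$text[2] - hdr$text[1] + 1)
  kw <- parse_fcs_text(raw_text)

  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stop_format("TEXT segment missing required keyword %s", key)
    v
  }
  mode <- toupper(need("$MODE"))
  if (mode != "L") stop_format("unsupported $MODE '%s' (only list mode L)", mode)
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D", "I"))
    stop_format("unsupported $DATATYPE '%s' (only F, D, I)", dtype)
  par <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))
  if (is.na(par) || is.na(tot) || par < 1 || tot < 0)
    stop_format("malformed $PAR/$TOT keywords")
  byteord <- gsub(" ", "", kw[["$BYTEORD"]] %||% "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  channels <- data.frame(
    index = seq_len(par),
    short_name = vapply(seq_len(par), function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), ""),
    marker = vapply(seq_len(par), function(i) kw[[sprintf("$P%dS", i)]] %||% "", ""),
    range = vapply(seq_len(par), function(i) as.numeric(kw[[sprintf("$P%dR", i)]] %||% "262144"), 0),
    stringsAsFactors = FALSE)

  data_beg <- hdr$data[1]
  data_end <- hdr$data[2]
  if (data_beg == 0) {
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  seek(con, data_beg)
  nvals <- par * tot
  if (dtype == "F") {
    vals <- readBin(con, "double", n = nvals, size = 4, endian = endian)
  } else if (dtype == "D") {
    vals <- readBin(con, "double", n = nvals, size = 8, endian = endian)
  } else {
    bits <- vapply(seq_len(par), function(i) as.integer(kw[[sprintf("$P%dB", i)]] %||% "32"), 0L)
    if (length(unique(bits)) != 1 || !unique(bits) %in% c(16L, 32L))
      stop_format("unsupported $PnB widths for $DATATYPE I: %s",
                  paste(unique(bits), collapse = ","))
    size <- unique(bits) / 8
    vals <- readBin(con, "integer", n = nvals, size = size, endian = endian,
                    signed = size == 4)
    vals <- as.double(vals)
    vals[vals < 0] <- vals[vals < 0] + 2^32  # recover unsigned 32-bit
  }
  if (length(vals) < nvals)
    stop_format("DATA segment truncated: expected %d values, read %d", nvals, length(vals))
  events <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)

  spill <- NULL
  for (key in c("$SPILLOVER", "SPILL", "$COMP")) {
    if (!is.null(kw[[key]])) { spill <- parse_spillover_keyword(kw[[key]]); break }
  }
  meta <- kw[!startsWith(names(kw), "$")]
  flow_sample(events, channels, spillover = spill,
              transform_state = "raw", metadata = meta)
}

#' Write a FlowSample to an FCS 3.1 file
#'
#' Always emits FCS 3.1, \code{$DATATYPE} F (little-endian float32), single
#' dataset. The sample's spillover matrix, when present, is stored under
#' \code{$SPILLOVER}; metadata keywords are carried as non-standard TEXT
#' keywords and survive a round trip.
#'
#' @param sample a \code{flow_sample} with at least one event and channel.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_fcs <- function(sample, path) {
  stopifnot(inherits(sample, "flow_sample"))
  if (nrow(sample$events) < 1 || ncol(sample$events) < 1)
    stop_validation("refusing to write an empty sample")
  d <- "|"
  par <- ncol(sample$events)
  tot <- nrow(sample$events)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(par), "$TOT" = as.character(tot))
  for (i in seq_len(par)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dN", i)] <- sample$channels$short_name[i]
    kw[sprintf("$P%dR", i)] <- format(sample$channels$range[i], scientific = FALSE)
    if (nzchar(sample$channels$marker[i]))
      kw[sprintf("$P%dS", i)] <- sample$channels$marker[i]
  }
  if (!is.null(sample$spillover)) {
    sp <- sample$spillover
    kw["$SPILLOVER"] <- paste(c(nrow(sp), colnames(sp), t(sp)), collapse = ",")
  }
  for (nm in names(sample$metadata)) {
    v <- sample$metadata[[nm]]
    if (length(v) == 1 && !grepl("|", as.character(v), fixed = TRUE))
      kw[toupper(nm)] <- as.character(v)
  }
  nbytes_data <- 4 * par * tot
  text_start <- 256  # fixed TEXT offset leaves room for the 58-byte header
  # two-pass offset calculation: data offsets appear inside TEXT
  build_text <- function(db, de) {
    kw2 <- c(kw, "$BEGINDATA" = as.character(db), "$ENDDATA" = as.character(de))
    paste0(d, paste0(names(kw2), d, unname(kw2), d, collapse = ""))
  }
  txt <- build_text(0, 0)
  for (i in 1:3) {
    data_beg <- text_start + nchar(txt, type = "bytes")
    data_end <- data_beg + nbytes_data - 1
    txt_new <- build_text(data_beg, data_end)
    if (nchar(txt_new, type = "bytes") == nchar(txt, type = "bytes")) { txt <- txt_new; break }
    txt <- txt_new
  }
  text_end <- text_start + nchar(txt, type = "bytes") - 1
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 text_start, text_end, data_beg, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(raw(text_start - nchar(hdr, type = "bytes")), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(sample$events)), con, size = 4, endian = "little")
  invisible(path)
}

#' Merge several FlowSamples into one
#'
#' Concatenates the event matrices of samples sharing the same channel
#' layout, the operation used to pool labeled reference files into a single
#' database file.
#'
#' @param samples list of \code{flow_sample} objects with identical channels.
#' @return A single \code{flow_sample}.
#' @export
merge_samples <- function(samples) {
  stopifnot(length(samples) >= 1)
  ref <- samples[[1]]
  for (s in samples[-1]) {
    if (!identical(s$channels$short_name, ref$channels$short_name))
      stop_validation("cannot merge samples with different channel layouts")
    if (!identical(s$transform_state, ref$transform_state))
      stop_validation("cannot merge samples in different transform states")
  }
  flow_sample(do.call(rbind, lapply(samples, function(s) s$events)),
              ref$channels, spillover = ref$spillover,
              transform_state = ref$transform_state,
              metadata = list(merged_from = length(samples)))
}

#' Read a spillover matrix from a CSV file
#'
#' Expects a header row and a leading column both carrying detector names.
#'
#' @param path CSV path.
#' @return Square numeric matrix with detector dimnames.
#' @export
read_spillover_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop_format("spillover CSV must be square")
  m
}

#' Apply spillover compensation
#'
#' Replaces the detector intensities by \code{events \%*\% solve(S)} where
#' \code{S} is the spillover matrix (rows = source detector, columns =
#' receiving detector, unit diagonal), i.e. standard linear unmixing in raw
#' intensity space. Only the detectors named by the spillover matrix are
#' touched.
#'
#' @param sample a \code{flow_sample} in the \code{raw} state.
#' @param spillover optional spillover matrix; defaults to the one embedded
#'   in the sample. An error is raised when neither exists.
#' @return The compensated \code{flow_sample} (state \code{compensated}).
#' @export
compensate <- function(sample, spillover = NULL) {
  stopifnot(inherits(sample, "flow_sample"))
  if (sample$transform_state != "raw")
    stop_validation("sample is already %s; compensation must start from raw data",
                    sample$transform_state)
  sp <- spillover %||% sample$spillover
  if (is.null(sp))
    stop_validation("no spillover matrix: none supplied and none embedded in the file")
  sp <- as.matrix(sp)
  dets <- colnames(sp)
  if (is.null(dets)) stop_validation("spillover matrix must carry detector names")
  missing <- setdiff(dets, sample$channels$short_name)
  if (length(missing))
    stop_validation("spillover names not present among detectors: %s",
                    paste(missing, collapse = ", "))
  kappa <- kappa(sp, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e8)
    stop_numerical("spillover matrix is numerically singular (condition number %.3g)", kappa)
  inv <- solve(sp)
  sample$events[, dets] <- sample$events[, dets, drop = FALSE] %*% inv
  sample$transform_state <- "compensated"
  sample$spillover <- sp
  sample
}

is_scatter_channel <- function(names) grepl("^(FSC|SSC)", names)

#' Transform fluorescence channels of a FlowSample
#'
#' Applies a monotone \code{\link{transform_spec}} to the selected channels.
#' Scatter channels (\code{FSC*}/\code{SSC*}) are left linear unless named
#' explicitly.
#'
#' @param sample a \code{flow_sample}, compensated (or raw when no spillover
#'   matrix exists anywhere).
#' @param spec a \code{\link{transform_spec}} (default logicle
#'   T=262144, W=0.5, M=4.5, A=0).
#' @param channels detector or marker names to transform; default all
#'   non-scatter channels.
#' @return The transformed \code{flow_sample} (state \code{transformed}).
#' @export
transform_sample <- function(sample, spec = transform_spec("logicle"),
                             channels = NULL) {
  stopifnot(inherits(sample, "flow_sample"), inherits(spec, "transform_spec"))
  if (sample$transform_state == "transformed")
    stop_validation("sample is already transformed")
  if (sample$transform_state == "raw" && !is.null(sample$spillover))
    stop_validation("sample carries a spillover matrix: compensate before transforming")
  ch_names <- sample$channels$short_name
  mk_names <- ifelse(nzchar(sample$channels$marker), sample$channels$marker, ch_names)
  if (is.null(channels)) {
    cols <- which(!is_scatter_channel(ch_names))
  } else {
    cols <- match(channels, ch_names)
    cols[is.na(cols)] <- match(channels[is.na(cols)], mk_names)
    if (anyNA(cols))
      stop_validation("unknown channel(s): %s", paste(channels[is.na(cols)], collapse = ", "))
  }
  for (j in cols) sample$events[, j] <- tf_forward(spec, sample$events[, j])
  sample$transform_state <- "transformed"
  sample$metadata$transform <- spec$kind
  sample
}
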