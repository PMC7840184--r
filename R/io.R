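#' Read a calibrated multi-channel stack from a multi-page TIFF
#'
#' The channel layout is never guessed: `metadata` declares it. With k
#' channels the page count must be divisible by k; pages are assigned
#' either round-robin (`layout = "interleaved"`: c1 t1, c2 t1, ..., c1 t2)
#' or in contiguous blocks (`layout = "blocks"`: all frames of channel 1,
#' then channel 2, ...).
#'
#' @param path multi-page TIFF path
#' @param metadata list with `channels` (character vector of labels),
#'   `dt` (s), `pixel_size` (um/px), optional `layout` (default
#'   "interleaved") and `t0_index` (1-based, default 1)
#' @return [TimeLapseRecording]
#' @export
read_stack <- function(path, metadata) {
  for (f in c("channels", "dt", "pixel_size")) {
    if (is.null(metadata[[f]])) stop("metadata field '", f, "' is required")
  }
  layout <- if (is.null(metadata$layout)) "interleaved" else metadata$layout
  if (!layout %in% c("interleaved", "blocks")) stop("unknown layout: ", layout)
  pages <- read_tiff(path)
  k <- length(metadata$channels)
  if (length(pages) %% k != 0L) {
    stop(length(pages), " pages not divisible by ", k, " declared channels")
  }
  Tn <- length(pages) %/% k
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  channels <- list()
  for (ci in seq_len(k)) {
    idx <- if (layout == "interleaved") seq(ci, by = k, length.out = Tn)
           else seq((ci - 1L) * Tn + 1L, length.out = Tn)
    arr <- array(0, c(H, W, Tn))
    for (t in seq_len(Tn)) arr[, , t] <- pages[[idx[t]]]
    channels[[metadata$channels[ci]]] <- arr
  }
  TimeLapseRecording(channels, dt = metadata$dt, pixel_size = metadata$pixel_size,
                     t0_index = if (is.null(metadata$t0_index)) 1L else metadata$t0_index)
}

#' Write a recording as a multi-page TIFF (inverse of [read_stack()])
#'
#' @param rec [TimeLapseRecording]
#' @param path output TIFF path
#' @param dtype sample type passed to [write_tiff()]
#' @param layout "interleaved" or "blocks" page order
#' @return the metadata list needed to read the file back
#' @export
write_stack <- function(rec, path, dtype = "float32", layout = "interleaved") {
  Tn <- n_frames(rec)
  k <- length(rec$channels)
  pages <- vector("list", Tn * k)
  for (ci in seq_len(k)) {
    idx <- if (layout == "interleaved") seq(ci, by = k, length.out = Tn)
           else seq((ci - 1L) * Tn + 1L, length.out = Tn)
    for (t in seq_len(Tn)) pages[[idx[t]]] <- rec$channels[[ci]][, , t]
  }
  write_tiff(pages, path, dtype = dtype)
  invisible(list(channels = names(rec$channels), dt = rec$dt,
                 pixel_size = rec$pixel_size, layout = layout,
                 t0_index = rec$t0_index))
}

#' Read an acquisition / stimulus config file (JSON)
#'
#' Expected top-level keys: `metadata` (see [read_stack()]) and optionally
#' `stimulus` with `onsets`, `duration`, `agent`, `concentration`.
#'
#' @param path JSON config path
#' @return list with `metadata` and (possibly NULL) `stimulus`
#'   ([StimulusProtocol])
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$metadata)) stop("config lacks 'metadata'")
  md <- doc$metadata
  if (!is.null(md$dt) && md$dt <= 0) stop("metadata dt must be > 0")
  if (!is.null(md$pixel_size) && md$pixel_size <= 0) stop("metadata pixel_size must be > 0")
  stim <- NULL
  if (!is.null(doc$stimulus)) {
    s <- doc$stimulus
    stim <- StimulusProtocol(s$onsets, s$duration,
                             agent = if (is.null(s$agent)) "ATP" else s$agent,
                             concentration = if (is.null(s$concentration)) 100 else s$concentration)
  }
  list(metadata = md, stimulus = stim)
}

# ---- result tables ---------------------------------------------------------

#' Convert a SignalTrace to a long-format data frame
#' @param trace [SignalTrace]
#' @return data.frame(roi, time_s, value, kind, convention)
#' @export
trace_to_df <- function(trace) {
  data.frame(
    roi = if (is.na(trace$roi)) "" else trace$roi,
    time_s = trace$times,
    value = trace$values,
    kind = trace$kind,
    convention = if (is.null(trace$meta$convention)) "" else trace$meta$convention,
    stringsAsFactors = FALSE
  )
}

#' Convert a FlowSeries to per-frame and per-transition data frames
#' @param fs [FlowSeries]
#' @return list of data.frame `s` (frame, time_s, s, s_smooth) and `c`
#'   (frame, time_s, c)
#' @export
flow_to_df <- function(fs) {
  n <- length(fs$s)
  list(
    s = data.frame(frame = seq_len(n), time_s = fs$times, s = fs$s,
                   s_smooth = fs$s_smooth),
    c = if (n >= 2L) {
      data.frame(frame = 2:n, time_s = fs$times[-1], c = fs$c)
    } else {
      data.frame(frame = integer(0), time_s = numeric(0), c = numeric(0))
    }
  )
}

#' Write result tables as CSV files
#'
#' Each element of `tables` (a named list of data frames) becomes
#' `<name>.csv` under `path`, with a header row and deterministic column
#' order (as given). Empty data frames yield header-only files.
#'
#' @param tables named list of data frames
#' @param path output directory (created if missing)
#' @return character vector of files written
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) stop("cannot create output directory: ", path)
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
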