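#' Write a stereo waveform as 32-bit float WAV
#'
#' Minimal RIFF/WAVE writer (format code 3, IEEE float, 2 channels,
#' interleaved).
#'
#' @param wf A `stereo_waveform` from [render_click_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stereo_wav <- function(wf, path) {
  stopifnot(inherits(wf, "stereo_waveform"),
            length(wf$left) == length(wf$right),
            all(is.finite(wf$left)), all(is.finite(wf$right)))
  n <- length(wf$left)
  fs <- as.integer(wf$sample_rate)
  interleaved <- as.numeric(rbind(wf$left, wf$right))
  data_bytes <- 4L * 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(2L, con, size = 2, endian = "little")            # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 8L, con, size = 4, endian = "little")       # byte rate
  writeBin(8L, con, size = 2, endian = "little")            # block align
  writeBin(32L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(interleaved, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float stereo WAV written by [write_stereo_wav()]
#'
#' @param path WAV file path.
#' @return A `stereo_waveform`.
#' @export
read_stereo_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 3 || fmt[2] != 2)
        stop("only 2-channel IEEE-float WAV supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", sz - 8)
    } else if (id == "data") {
      x <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      m <- matrix(x, nrow = 2)
      return(structure(list(left = m[1, ], right = m[2, ],
                            sample_rate = fs),
                       class = "stereo_waveform"))
    } else {
      readBin(con, "raw", sz)
    }
  }
}

#' Export a rendered stimulus with sidecar metadata
#'
#' Writes `<prefix>.wav` (32-bit float stereo) and `<prefix>.json`
#' holding the click-train specification fields.
#'
#' @param spec A [click_train_spec()].
#' @param prefix Output path prefix (without extension).
#' @return Character vector of the two written paths, invisibly.
#' @export
export_stimulus <- function(spec, prefix) {
  stopifnot(inherits(spec, "click_train_spec"))
  wav <- paste0(prefix, ".wav")
  json <- paste0(prefix, ".json")
  write_stereo_wav(render_click_train(spec), wav)
  jsonlite::write_json(unclass(spec), json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(wav, json))
}

#' Write an event table as TSV
#'
#' Native dialect uses columns `trial_index`, `onset_s`, `condition`,
#' `is_target`; the BIDS dialect writes `onset`, `duration`,
#' `trial_type`, `is_target` (events.tsv column naming).
#'
#' @param events An [make_run_events()] table.
#' @param path Output file path.
#' @param dialect `"native"` or `"bids"`.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path,
                             dialect = c("native", "bids")) {
  dialect <- match.arg(dialect)
  trial_dur <- attr(events, "trial_dur")
  if (is.null(trial_dur)) trial_dur <- 1
  df <- if (dialect == "native") {
    events[, c("trial_index", "onset_s", "condition", "is_target")]
  } else {
    data.frame(onset = events$onset_s, duration = trial_dur,
               trial_type = events$condition,
               is_target = events$is_target)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV (native or BIDS dialect)
#'
#' @param path TSV file path.
#' @param trial_dur Trial duration, used when the file carries none.
#' @return An `event_table` data frame.
#' @export
read_events_tsv <- function(path, trial_dur = 1) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  if ("onset" %in% names(df)) {                      # BIDS dialect
    if ("duration" %in% names(df) && nrow(df) > 0)
      trial_dur <- df$duration[1]
    df <- data.frame(trial_index = seq_len(nrow(df)),
                     onset_s = df$onset,
                     condition = as.character(df$trial_type),
                     is_target = if ("is_target" %in% names(df))
                       as.logical(df$is_target) else FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df$condition <- as.character(df$condition)
    df$is_target <- as.logical(df$is_target)
  }
  df$is_warmup <- logical(nrow(df))
  attr(df, "trial_dur") <- trial_dur
  attr(df, "run_duration") <- if (nrow(df) > 0)
    max(df$onset_s) + trial_dur else 0
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write trial betas as long-format TSV
#'
#' Columns: `subject`, `run`, `roi`, `hemisphere`, `trial`, `condition`,
#' `voxel`, `beta`.  Excluded trials are omitted.
#'
#' @param tb A [extract_trial_betas()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_betas <- function(tb, path) {
  stopifnot(inherits(tb, "trial_betas"))
  keep <- !tb$excluded
  b <- tb$beta[keep, , drop = FALSE]
  nt <- nrow(b)
  nv <- ncol(b)
  vox <- tb$voxels
  df <- data.frame(
    subject = tb$subject, run = tb$run,
    roi = if (!is.null(vox)) rep(vox$roi, each = nt) else NA,
    hemisphere = if (!is.null(vox)) rep(vox$hemisphere, each = nt) else NA,
    trial = rep(which(keep), times = nv),
    condition = rep(tb$condition[keep], times = nv),
    voxel = if (!is.null(vox)) rep(vox$voxel_id, each = nt)
            else rep(seq_len(nv), each = nt),
    beta = as.vector(b))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read trial betas from long-format TSV
#'
#' Inverse of [write_trial_betas()] for a single subject/run.
#'
#' @param path TSV file path.
#' @return A `trial_betas` object.
#' @export
read_trial_betas <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  vox_ids <- unique(df$voxel)
  trials <- sort(unique(df$trial))
  b <- matrix(NA_real_, length(trials), length(vox_ids),
              dimnames = list(NULL, vox_ids))
  cond <- character(length(trials))
  for (j in seq_along(vox_ids)) {
    sub <- df[df$voxel == vox_ids[j], ]
    ord <- match(trials, sub$trial)
    b[, j] <- sub$beta[ord]
    if (j == 1) cond <- as.character(sub$condition[ord])
  }
  vox_meta <- unique(df[, c("voxel", "roi", "hemisphere")])
  names(vox_meta)[1] <- "voxel_id"
  structure(list(beta = b, condition = cond,
                 ild = suppressWarnings(as.numeric(cond)),
                 excluded = logical(length(trials)),
                 is_warmup = logical(length(trials)),
                 voxels = vox_meta[match(vox_ids, vox_meta$voxel_id), ],
                 subject = df$subject[1], run = df$run[1], mode = NA),
            class = "trial_betas")
}
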