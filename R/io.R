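# Readers and writers for the package's plain-text interchange formats:
# landmarks and signals as CSV, events and timelines as JSON, images as
# PGM/PNG (see images.R), configs as YAML or JSON.

#' Read or write per-frame eye landmarks as CSV
#'
#' Columns: frame_index (0-based), x1,y1,...,x6,y6 (pixels, origin top-left,
#' y increasing downward), one row per frame in frame order.
#'
#' @param frames list of 6 x 2 landmark matrices.
#' @param path CSV file path.
#' @return \code{readLandmarksCsv}: a list of landmark matrices;
#'   \code{writeLandmarksCsv}: the path, invisibly.
#' @export
writeLandmarksCsv <- function(frames, path) {
  m <- t(vapply(frames, function(lm) as.vector(t(lm)), numeric(12)))
  colnames(m) <- paste0(rep(c("x", "y"), 6), rep(1:6, each = 2))
  df <- cbind(data.frame(frame_index = seq_along(frames) - 1L), m)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLandmarksCsv
#' @export
readLandmarksCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- paste0(rep(c("x", "y"), 6), rep(1:6, each = 2))
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns frame_index, x1,y1,...,x6,y6")
  df <- df[order(df$frame_index), ]
  lapply(seq_len(nrow(df)), function(i)
    matrix(as.numeric(df[i, need]), ncol = 2, byrow = TRUE,
           dimnames = list(paste0("p", 1:6), c("x", "y"))))
}

#' Read or write an EAR series as CSV (frame_index, ear)
#'
#' @param s an \linkS4class{EarSeries}.
#' @param path CSV file path.
#' @param frameRate frame rate to attach on reading (the CSV carries frame
#'   indices only).
#' @return \code{readEarSeriesCsv}: an \linkS4class{EarSeries};
#'   \code{writeEarSeriesCsv}: the path, invisibly.
#' @export
writeEarSeriesCsv <- function(s, path) {
  utils::write.csv(data.frame(frame_index = seq_along(earValues(s)) - 1L,
                              ear = earValues(s)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEarSeriesCsv
#' @export
readEarSeriesCsv <- function(path, frameRate = 25) {
  df <- utils::read.csv(path)
  EarSeries(df$ear[order(df$frame_index)], frameRate = frameRate)
}

#' Read or write an EOG stream as CSV (time_s, eog1, eog2, eog3)
#'
#' The sample rate is recovered from the time column on reading.
#'
#' @param stream an \linkS4class{EogStream}.
#' @param path CSV file path.
#' @return \code{readEogCsv}: an \linkS4class{EogStream};
#'   \code{writeEogCsv}: the path, invisibly.
#' @export
writeEogCsv <- function(stream, path) {
  ch <- channelMatrix(stream)
  fs <- sampleRate(stream)
  utils::write.csv(data.frame(time_s = (seq_len(nrow(ch)) - 1L) / fs,
                              eog1 = ch[, 1], eog2 = ch[, 2],
                              eog3 = ch[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEogCsv
#' @export
readEogCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "eog1", "eog2", "eog3")
  if (!all(need %in% names(df)))
    stop("EOG CSV must have columns time_s, eog1, eog2, eog3")
  dt <- stats::median(diff(df$time_s))
  EogStream(df$eog1, df$eog2, df$eog3, sampleRate = 1 / dt)
}

#' Read or write an EEG trace as CSV (time_s, amplitude)
#'
#' @param ep an \linkS4class{EegEpoch}.
#' @param path CSV file path.
#' @return \code{readEegCsv}: an \linkS4class{EegEpoch};
#'   \code{writeEegCsv}: the path, invisibly.
#' @export
writeEegCsv <- function(ep, path) {
  fs <- sampleRate(ep)
  utils::write.csv(data.frame(time_s = (seq_along(eegSamples(ep)) - 1L) / fs,
                              amplitude = eegSamples(ep)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEegCsv
#' @export
readEegCsv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("EEG CSV must have columns time_s, amplitude")
  EegEpoch(df$amplitude, sampleRate = 1 / stats::median(diff(df$time_s)))
}

#' Read or write event lists as JSON
#'
#' Events are objects \code{{time_s, duration_s, source}}.
#'
#' @param events data.frame with those columns.
#' @param path JSON file path.
#' @return \code{readEventsJson}: the events data.frame;
#'   \code{writeEventsJson}: the path, invisibly.
#' @export
writeEventsJson <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname writeEventsJson
#' @export
readEventsJson <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(df))
    df <- data.frame(time_s = numeric(), duration_s = numeric(),
                     source = character())
  df
}

#' Write a decision timeline (and optional warnings) as JSON
#'
#' @param tl a \linkS4class{DecisionTimeline}.
#' @param path JSON file path.
#' @param warnings optional warning-event data.frame from
#'   \code{\link{emitWarnings}}.
#' @return the path, invisibly.
#' @export
writeTimelineJson <- function(tl, path, warnings = NULL) {
  obj <- list(windows = timelineWindows(tl))
  if (!is.null(warnings)) obj$warnings <- warnings
  jsonlite::write_json(obj, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Write or load a complete synthetic session as files
#'
#' Materializes a generated session in the exact formats the analysis
#' modules read: landmarks CSV, eye images as PGM plus a manifest CSV
#' (path,label,time_s), EOG CSV, EEG CSV, and a ground-truth JSON holding
#' the scenario (blink times, drowsy windows, seed).
#'
#' @param session list from \code{\link{genSession}}.
#' @param dir output directory (created if needed).
#' @return \code{writeSession}: \code{dir}, invisibly; \code{loadSession}: a
#'   session list of the same shape as \code{\link{genSession}} returns
#'   (minus the scenario's SNRs, which live in the ground-truth file).
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLandmarksCsv(session$landmarks, file.path(dir, "landmarks.csv"))
  imgDir <- file.path(dir, "images")
  dir.create(imgDir, showWarnings = FALSE)
  paths <- vapply(seq_along(session$images), function(i) {
    p <- file.path("images", sprintf("frame_%04d.pgm", i))
    writeEyeImage(session$images[[i]], file.path(dir, p))
    p
  }, character(1))
  utils::write.csv(
    data.frame(path = paths,
               label = vapply(session$images, imageLabel, character(1)),
               time_s = session$imageTimes),
    file.path(dir, "images.csv"), row.names = FALSE)
  writeEogCsv(session$eog$stream, file.path(dir, "eog.csv"))
  writeEegCsv(session$eeg, file.path(dir, "eeg.csv"))
  sc <- session$scenario
  jsonlite::write_json(
    list(duration = sc@duration, blink_times = sc@blinkTimes,
         drowsy_windows = apply(sc@drowsyWindows, 1L, function(r)
           list(start = r[[1]], end = r[[2]])),
         frame_rate = session$frameRate, seed = sc@seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSession
#' @export
loadSession <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  manifest <- utils::read.csv(file.path(dir, "images.csv"))
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- readEyeImage(file.path(dir, manifest$path[i]))
    EyeImage(imageRaster(img), label = manifest$label[i],
             sourceSize = dim(imageRaster(img)))
  })
  list(landmarks = readLandmarksCsv(file.path(dir, "landmarks.csv")),
       frameRate = gt$frame_rate,
       images = images, imageTimes = manifest$time_s,
       eog = list(stream = readEogCsv(file.path(dir, "eog.csv")),
                  events = data.frame(time_s = as.numeric(gt$blink_times))),
       eeg = readEegCsv(file.path(dir, "eeg.csv")),
       groundTruth = gt)
}
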