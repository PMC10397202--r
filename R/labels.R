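#' Construct a movement-label stream
#'
#' Per-frame movement-module labels over the 40-class vocabulary produced by
#' upstream movement segmentation.
#'
#' @param labels integer vector, one label per frame.
#' @param vocabulary_size number of movement classes (default 40).
#' @return An object of class `movement_labels`.
#' @export
movement_labels <- function(labels, vocabulary_size = 40) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("empty label stream", call. = FALSE)
  if (anyNA(labels)) stop("NA labels", call. = FALSE)
  if (any(labels < 1L | labels > vocabulary_size))
    stop("labels must lie in 1..", vocabulary_size, call. = FALSE)
  structure(list(labels = labels, vocabulary_size = as.integer(vocabulary_size)),
            class = "movement_labels")
}

#' @export
print.movement_labels <- function(x, ...) {
  cat("Movement labels: ", length(x$labels), " frames, ",
      length(unique(x$labels)), " of ", x$vocabulary_size,
      " classes used\n", sep = "")
  invisible(x)
}

#' Convert a label stream to a segment table
#'
#' @param stream a [movement_labels()].
#' @return data.frame with columns `start`, `end` (1-based inclusive frames)
#'   and `label`.
#' @export
labels_to_segments <- function(stream) {
  l <- stream$labels
  r <- rle(l)
  end <- cumsum(r$lengths)
  data.frame(start = c(1L, head(end, -1L) + 1L), end = end,
             label = r$values)
}

#' Convert a segment table to a dense label stream
#'
#' Segments are 1-based inclusive, must not overlap and must tile
#' `1..n_frames` without gaps.
#'
#' @param segments data.frame with `start`, `end`, `label`.
#' @param n_frames total frame count.
#' @param vocabulary_size number of movement classes.
#' @return A [movement_labels()].
#' @export
segments_to_labels <- function(segments, n_frames, vocabulary_size = 40) {
  seg <- segments[order(segments$start), , drop = FALSE]
  if (any(seg$end < seg$start))
    stop("segment with end < start", call. = FALSE)
  if (nrow(seg) > 1L) {
    ov <- which(seg$start[-1L] <= seg$end[-nrow(seg)])
    if (length(ov))
      stop("overlapping segments at rows ", ov[1], " and ", ov[1] + 1L,
           " (sorted order)", call. = FALSE)
  }
  covered <- c(seg$start[1] == 1L,
               if (nrow(seg) > 1L) seg$start[-1L] == seg$end[-nrow(seg)] + 1L,
               seg$end[nrow(seg)] == n_frames)
  if (!all(covered))
    stop("segments do not cover frames 1..", n_frames, " without gaps",
         call. = FALSE)
  out <- integer(n_frames)
  for (i in seq_len(nrow(seg)))
    out[seg$start[i]:seg$end[i]] <- seg$label[i]
  movement_labels(out, vocabulary_size = vocabulary_size)
}

#' Read a movement-label stream from CSV
#'
#' Accepts either a dense table (`frame`, `label`) or a segment table
#' (`start`, `end`, `label`; 1-based inclusive), auto-detected from the
#' header.
#'
#' @param path file path.
#' @param n_frames expected frame count.
#' @param vocabulary_size number of movement classes.
#' @return A [movement_labels()].
#' @export
read_labels <- function(path, n_frames, vocabulary_size = 40) {
  df <- utils::read.csv(path)
  if (all(c("start", "end", "label") %in% names(df))) {
    segments_to_labels(df, n_frames, vocabulary_size)
  } else if (all(c("frame", "label") %in% names(df))) {
    if (nrow(df) != n_frames)
      stop("dense label file has ", nrow(df), " rows, expected ", n_frames,
           call. = FALSE)
    df <- df[order(df$frame), ]
    if (!identical(as.integer(df$frame), seq_len(n_frames)))
      stop("dense label file frames are not 1..", n_frames, call. = FALSE)
    movement_labels(df$label, vocabulary_size = vocabulary_size)
  } else {
    stop("label file must have columns (frame, label) or (start, end, label)",
         call. = FALSE)
  }
}

#' Write a movement-label stream to CSV
#'
#' @param stream a [movement_labels()].
#' @param path output file path.
#' @param format `"segments"` (default, compact run-length table) or
#'   `"dense"`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(stream, path, format = c("segments", "dense")) {
  format <- match.arg(format)
  df <- if (format == "segments") labels_to_segments(stream)
        else data.frame(frame = seq_along(stream$labels), label = stream$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
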