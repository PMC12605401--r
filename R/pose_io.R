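#' Construct a pose track
#'
#' A pose track holds, for one recorded session, the estimated image
#' coordinates (pixels) and likelihood of every tracked landmark at every
#' frame. Frames are 0-based and strictly increasing; every frame carries an
#' entry for every landmark, with missing detections coded as `NA`
#' coordinates and likelihood 0.
#'
#' @param data Data frame with columns `frame`, `landmark`, `x`, `y`,
#'   `likelihood` (long layout, one row per frame x landmark).
#' @param fps Frames per second (> 0), default 25.
#' @param session_id Session identifier string.
#' @return An object of class `pose_track`: the validated long data frame
#'   with attributes `fps`, `session_id` and `landmarks`.
#' @export
pose_track <- function(data, fps = 25, session_id = "session") {
  stopifnot(is.data.frame(data),
            all(c("frame", "landmark", "x", "y", "likelihood") %in%
                names(data)),
            is.numeric(fps), fps > 0)
  data$landmark <- as.character(data$landmark)
  landmarks <- unique(data$landmark)
  for (need in c("snout", "mid_body")) {
    if (!need %in% landmarks) {
      stop("pose track must include landmark '", need, "'")
    }
  }
  frames <- unique(data$frame)
  if (is.unsorted(frames, strictly = TRUE)) {
    stop("frame indices must be strictly increasing")
  }
  if (nrow(data) != length(frames) * length(landmarks)) {
    stop("every frame must carry one entry per landmark")
  }
  # missing-coding: x/y absent together, likelihood forced to 0
  miss <- is.na(data$x) | is.na(data$y) | is.na(data$likelihood)
  data$x[miss] <- NA_real_
  data$y[miss] <- NA_real_
  data$likelihood[miss] <- 0
  if (any(data$likelihood < 0 | data$likelihood > 1)) {
    stop("likelihood values must lie in [0, 1]")
  }
  data <- data[order(data$frame, match(data$landmark, landmarks)), ,
               drop = FALSE]
  rownames(data) <- NULL
  structure(data, fps = fps, session_id = session_id,
            landmarks = landmarks, class = c("pose_track", "data.frame"))
}

#' Frame rate, session id and landmark set of a pose track
#' @param track A `pose_track`.
#' @return `track_fps`: numeric fps; `track_landmarks`: character vector.
#' @export
track_fps <- function(track) attr(track, "fps")

#' @rdname track_fps
#' @export
track_landmarks <- function(track) attr(track, "landmarks")

#' Extract one landmark from a pose track as a frame-ordered matrix
#'
#' @param track A `pose_track`.
#' @param name Landmark name.
#' @return Data frame `frame`, `x`, `y`, `likelihood`, one row per frame.
#' @export
landmark_series <- function(track, name) {
  stopifnot(name %in% track_landmarks(track))
  out <- track[track$landmark == name, c("frame", "x", "y", "likelihood")]
  rownames(out) <- NULL
  out
}

#' Read a pose-track table
#'
#' Supports the two tabular layouts produced around markerless
#' pose-estimation workflows:
#' * `flat_csv` — columns `frame,landmark,x,y,likelihood`;
#' * `dlc_csv` — the de-facto pose-estimation export: three header rows
#'   (scorer / bodyparts / coords), first column the frame index, then an
#'   `x,y,likelihood` triplet per landmark.
#'
#' Cells with missing coordinates are missing-coded (`NA` coordinates,
#' likelihood 0). The landmark set must include `snout` and `mid_body`.
#'
#' @param path Path to the table.
#' @param dialect One of `"flat_csv"`, `"dlc_csv"`, `"hdf5"` (the latter is
#'   not supported in this build and raises an error).
#' @param fps Frames per second to record on the track (default 25).
#' @param session_id Session identifier (defaults to the file name).
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, dialect = c("flat_csv", "dlc_csv", "hdf5"),
                            fps = 25, session_id = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (is.null(session_id)) {
    session_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "hdf5") {
    stop("hdf5 pose tables are not supported in this build; ",
         "export to flat_csv or dlc_csv instead")
  }
  df <- if (dialect == "flat_csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    read_dlc_csv(path)
  }
  pose_track(df, fps = fps, session_id = session_id)
}

read_dlc_csv <- function(path) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(raw) < 4) stop("dlc_csv requires 3 header rows plus data")
  bodyparts <- as.character(raw[2, -1])
  coords <- as.character(raw[3, -1])
  if (!all(coords %in% c("x", "y", "likelihood"))) {
    stop("dlc_csv coords header row must contain x/y/likelihood")
  }
  body <- raw[-(1:3), , drop = FALSE]
  frame <- as.integer(body[[1]])
  if (anyNA(frame)) stop("non-integer frame index in dlc_csv")
  landmarks <- unique(bodyparts)
  pieces <- lapply(landmarks, function(lm) {
    idx <- which(bodyparts == lm)
    cols <- stats::setNames(idx, coords[idx])
    if (!all(c("x", "y", "likelihood") %in% names(cols))) {
      stop("landmark ", lm, " lacks a complete x/y/likelihood triplet")
    }
    data.frame(
      frame = frame, landmark = lm,
      x = suppressWarnings(as.numeric(body[[cols[["x"]] + 1]])),
      y = suppressWarnings(as.numeric(body[[cols[["y"]] + 1]])),
      likelihood = suppressWarnings(as.numeric(body[[cols[["likelihood"]] + 1]])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

#' Write a pose track as flat_csv
#'
#' Numbers are serialized with 17 significant digits so that a
#' `write_pose_table()` / [read_pose_table()] round-trip reproduces
#' coordinates and likelihoods bit-exactly.
#'
#' @param track A `pose_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("frame,landmark,x,y,likelihood",
             sprintf("%d,%s,%s,%s,%s", track$frame, track$landmark,
                     fmt(track$x), fmt(track$y), fmt(track$likelihood)))
  writeLines(lines, path)
  invisible(path)
}
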