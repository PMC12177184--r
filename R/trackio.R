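# Tracking-data containers and delimited-text IO.
#
# Conventions: SI units throughout (m, s); y axis points UP (gravity acts in
# -y), so files holding image coordinates (y down) must be read with
# y_flip = TRUE.  Frame indexing is 0-based; the time column of a file is
# treated as a consistency check only and is always recomputed as
# frame / frame_rate.

.point_labels <- c("head", "abdomen_tip", "ftj", "tarsus")

.wide_cols <- c("frame", "t",
                "head_x", "head_y", "abdomen_x", "abdomen_y",
                "ftj_x", "ftj_y", "tarsus_x", "tarsus_y")

# map long-layout point labels to wide column stems
.label_stem <- c(head = "head", abdomen_tip = "abdomen",
                 ftj = "ftj", tarsus = "tarsus")

#' Construct a tracked trajectory
#'
#' A tracked trajectory holds, for one jump, the per-frame positions of the
#' four digitized body points (head, abdomen tip, femorotibial joint,
#' tarsus) in SI units, together with the frame rate and jump metadata.
#'
#' @param frames data frame with columns `frame`, `head_x`, `head_y`,
#'   `abdomen_x`, `abdomen_y`, `ftj_x`, `ftj_y`, `tarsus_x`, `tarsus_y`
#'   (a `t` column, if present, is checked against `frame / frame_rate`
#'   and then recomputed). Coordinates in metres.
#' @param frame_rate recording frame rate in Hz.
#' @param jump_id,animal_id,sex,target_height jump metadata. `sex` is
#'   `"M"`, `"F"` or `NA`; `target_height` is the overhead target height in
#'   metres (`NA` when not applicable).
#'
#' @return An object of class `track_trajectory`: a list with elements
#'   `data` (the per-frame wide table), `frame_rate`, `jump_id`,
#'   `animal_id`, `sex` and `target_height`.
#' @export
track_trajectory <- function(frames, frame_rate,
                             jump_id = NA_character_,
                             animal_id = NA_character_,
                             sex = NA_character_,
                             target_height = NA_real_) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  frames <- as.data.frame(frames)
  need <- setdiff(.wide_cols, "t")
  missing_cols <- setdiff(need, names(frames))
  if (length(missing_cols) > 0L)
    stop("missing trajectory columns: ", paste(missing_cols, collapse = ", "))
  if (!is.na(sex) && !sex %in% c("M", "F"))
    stop("sex must be 'M', 'F' or NA")
  if (nrow(frames) > 0L) {
    if (any(frames$frame != round(frames$frame)))
      stop("frame indices must be integers")
    frames$frame <- as.integer(round(frames$frame))
    ord <- order(frames$frame)
    frames <- frames[ord, , drop = FALSE]
    if (anyDuplicated(frames$frame))
      stop("non-monotonic frame index: duplicated frames")
    if ("t" %in% names(frames)) {
      bad <- abs(frames$t - frames$frame / frame_rate) > 1e-9
      if (any(bad, na.rm = TRUE))
        warning("time column inconsistent with frame/frame_rate at ",
                sum(bad), " frame(s); recomputed")
    }
  }
  frames$t <- frames$frame / frame_rate
  frames <- frames[, .wide_cols, drop = FALSE]
  rownames(frames) <- NULL
  structure(list(data = frames, frame_rate = frame_rate,
                 jump_id = jump_id, animal_id = animal_id, sex = sex,
                 target_height = target_height),
            class = "track_trajectory")
}

#' @export
print.track_trajectory <- function(x, ...) {
  cat("<track_trajectory> jump", x$jump_id, "animal", x$animal_id, "\n")
  cat("  frames:", nrow(x$data), " frame rate:", x$frame_rate, "Hz\n")
  if (!is.na(x$target_height))
    cat("  target height:", x$target_height * 1000, "mm\n")
  invisible(x)
}

#' Per-animal morphometrics table
#'
#' Validates a morphometrics table (one row per animal) with columns
#' `animal_id`, `mass` (kg), `body_length` (m; antenna base to most distal
#' point of the abdomen), `femur_length` (m) and `tibia_length` (m).
#'
#' @param x data frame to validate.
#' @return `x`, invisibly coerced to a plain data frame.
#' @export
morphometrics <- function(x) {
  x <- as.data.frame(x)
  need <- c("animal_id", "mass", "body_length", "femur_length", "tibia_length")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("missing morphometrics columns: ", paste(miss, collapse = ", "))
  num <- c("mass", "body_length", "femur_length", "tibia_length")
  for (col in num)
    if (any(!is.finite(x[[col]]) | x[[col]] <= 0))
      stop("morphometrics column '", col, "' must be strictly positive")
  x
}

# parse a character column to numeric, reporting the 1-based file line of
# the first failure (line 1 is the header)
.parse_numeric <- function(x, col, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L)
    stop("unparseable numeric in '", path, "', column '", col,
         "', line ", bad[1L] + 1L, ": '", x[bad[1L]], "'")
  v
}

#' Read a digitized trajectory from delimited text
#'
#' Accepts either the wide layout (columns `frame,t,head_x,head_y,
#' abdomen_x,abdomen_y,ftj_x,ftj_y,tarsus_x,tarsus_y`) or the long layout
#' (columns `frame,t,point,x,y` with point labels `head`, `abdomen_tip`,
#' `ftj`, `tarsus`).  Coordinates are multiplied by `scale` to convert the
#' file's length unit to metres; e.g. a file in mm is read with
#' `scale = 0.001`.
#'
#' @param path path to a comma-delimited text file with a header row.
#' @param scale metres per file length unit (> 0).
#' @param frame_rate recording frame rate in Hz.
#' @param y_flip flip the y axis (for files in image coordinates, y down).
#' @param jump_id,animal_id,sex,target_height metadata passed to
#'   [track_trajectory()].
#' @return A [track_trajectory()] in SI units, rows sorted by frame.
#' @export
read_trajectory <- function(path, scale = 1, frame_rate = 2000,
                            y_flip = FALSE,
                            jump_id = NA_character_,
                            animal_id = NA_character_,
                            sex = NA_character_,
                            target_height = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  if ("point" %in% names(raw)) {
    need <- c("frame", "point", "x", "y")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0L)
      stop("long-layout file missing columns: ", paste(miss, collapse = ", "))
    frame <- .parse_numeric(raw$frame, "frame", path)
    x <- .parse_numeric(raw$x, "x", path)
    y <- .parse_numeric(raw$y, "y", path)
    bad_label <- setdiff(unique(raw$point), .point_labels)
    if (length(bad_label) > 0L)
      stop("unknown point label(s): ", paste(bad_label, collapse = ", "))
    frames <- sort(unique(frame))
    wide <- data.frame(frame = frames)
    for (lab in .point_labels) {
      sel <- raw$point == lab
      if (anyDuplicated(frame[sel]))
        stop("duplicate rows for point '", lab, "'")
      idx <- match(frames, frame[sel])
      if (anyNA(idx)) {
        f_missing <- frames[which(is.na(idx))[1L]]
        stop("frame ", f_missing, ": missing point label '", lab, "'")
      }
      stem <- .label_stem[[lab]]
      wide[[paste0(stem, "_x")]] <- x[sel][idx]
      wide[[paste0(stem, "_y")]] <- y[sel][idx]
    }
    # long files are expected frame-major; a frame appearing after a later
    # frame is a digitization error
    per_frame_first <- tapply(seq_along(frame), frame, min)
    if (is.unsorted(per_frame_first[as.character(frames)]))
      stop("non-monotonic frame index")
  } else {
    need <- setdiff(.wide_cols, "t")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0L)
      stop("wide-layout file missing columns: ", paste(miss, collapse = ", "))
    wide <- data.frame(frame = .parse_numeric(raw$frame, "frame", path))
    for (col in setdiff(need, "frame"))
      wide[[col]] <- .parse_numeric(raw[[col]], col, path)
    if (is.unsorted(wide$frame, strictly = TRUE))
      stop("non-monotonic frame index")
  }
  coord_cols <- setdiff(names(wide), "frame")
  for (col in coord_cols) wide[[col]] <- wide[[col]] * scale
  if (isTRUE(y_flip))
    for (col in grep("_y$", coord_cols, value = TRUE))
      wide[[col]] <- -wide[[col]]
  track_trajectory(wide, frame_rate = frame_rate, jump_id = jump_id,
                   animal_id = animal_id, sex = sex,
                   target_height = target_height)
}

.format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a trajectory as wide-layout CSV
#'
#' Writes SI-unit coordinates at full double precision so that
#' `read_trajectory(write_trajectory(traj))` reproduces every coordinate.
#'
#' @param traj a [track_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "track_trajectory"))
  d <- traj$data
  lines <- paste(.wide_cols, collapse = ",")
  if (nrow(d) > 0L) {
    body <- do.call(paste, c(lapply(.wide_cols, function(col) {
      if (col == "frame") format(d[[col]], scientific = FALSE, trim = TRUE)
      else .format_num(d[[col]])
    }), sep = ","))
    lines <- c(lines, body)
  }
  ok <- tryCatch({
    writeLines(lines, path); TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a per-jump results table
#'
#' One delimited row per jump with a header.  All values are in SI units
#' except `rot_fraction`, which is a percentage.
#'
#' @param records a data frame, or a list of identically-named lists, of
#'   per-jump results (e.g. rows from [analyze_jump()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) == 0L) {
      df <- data.frame(jump_id = character(0))
    } else {
      keys <- names(records[[1L]])
      for (i in seq_along(records)) {
        if (!identical(sort(names(records[[i]])), sort(keys)))
          stop("heterogeneous record keys at record ", i, ": ",
               paste(names(records[[i]]), collapse = ", "))
      }
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r[keys], stringsAsFactors = FALSE)))
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (col in names(df)[num]) out[[col]] <- .format_num(df[[col]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return data frame of per-jump results.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
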