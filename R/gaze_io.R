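#' Segment condition vocabulary
#'
#' Labels a drive's experimental segments can carry: an undistracted
#' calibration interval (`"baseline"`), plain driving (`"no_task"`), driving
#' with a cognitively loading side task (`"cognitive_task"`), or with a
#' visually loading one (`"visual_task"`).
#'
#' @export
segment_conditions <- c("baseline", "no_task", "cognitive_task", "visual_task")

#' Build a validated gaze stream
#'
#' A gaze stream is a tibble with one row per eye-tracker sample: time `t`
#' in seconds, the area-of-interest label `aoi` the sample falls in
#' (`"none"` when outside every AOI), and a `valid` quality flag. The
#' nominal sampling rate is carried as an attribute so downstream smoothing
#' can convert seconds to sample counts.
#'
#' @param samples Data frame with columns `t` (seconds, non-decreasing,
#'   no duplicates), `aoi` (character), and optionally `valid` (logical,
#'   default `TRUE`) and gaze-plane coordinates `x`, `y`.
#' @param rate_hz Nominal sampling frequency in Hz. When `NULL` it is
#'   inferred as `1 / median(diff(t))` and a message is emitted. A supplied
#'   rate that disagrees with the median sample spacing by more than 20%
#'   triggers a warning.
#' @return A tibble of class `gaze_stream` with attribute `rate_hz`.
#' @examples
#' gaze_stream(data.frame(t = c(0, .1, .2), aoi = c("dashboard", "none", "none")))
#' @export
gaze_stream <- function(samples, rate_hz = NULL) {
  samples <- as_tibble(samples)
  if (!all(c("t", "aoi") %in% names(samples))) {
    stop_format("a gaze stream needs columns `t` and `aoi`")
  }
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  t <- samples$t
  if (length(t) > 0) {
    if (anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
      stop_data("timestamps must be finite and non-negative")
    }
    bad <- which(diff(t) < 0)
    if (length(bad) > 0) {
      stop_data(sprintf("timestamps not monotone: row %d (t = %g) precedes row %d (t = %g)",
                        bad[1] + 1L, t[bad[1] + 1L], bad[1], t[bad[1]]))
    }
    if (anyDuplicated(t)) stop_data("duplicate timestamps are not allowed")
  }
  samples$aoi <- as.character(samples$aoi)
  samples$valid <- as.logical(samples$valid)

  spacing <- if (length(t) > 1) median(diff(t)) else NA_real_
  if (is.null(rate_hz)) {
    if (!is.na(spacing) && spacing > 0) {
      rate_hz <- 1 / spacing
      rlang::inform(sprintf("inferred rate_hz = %.4g from median sample spacing", rate_hz))
    } else {
      stop_config("rate_hz cannot be inferred from fewer than 2 samples; supply it")
    }
  } else {
    if (!is.numeric(rate_hz) || length(rate_hz) != 1 || !is.finite(rate_hz) || rate_hz <= 0) {
      stop_config("rate_hz must be a single positive number")
    }
    if (!is.na(spacing) && spacing > 0 && abs(1 / spacing - rate_hz) > 0.2 * rate_hz) {
      warn(sprintf("declared rate_hz = %g disagrees with median spacing (%.4g Hz) by more than 20%%",
                   rate_hz, 1 / spacing))
    }
  }
  structure(samples, rate_hz = as.numeric(rate_hz),
            class = c("gaze_stream", class(samples)))
}

#' Sampling rate of a gaze stream
#' @param stream A `gaze_stream`.
#' @return The nominal sampling frequency in Hz.
#' @export
rate_hz <- function(stream) attr(stream, "rate_hz", exact = TRUE)

#' Define areas of interest
#'
#' @param ... Named polygons: each argument is a two-column matrix (or a
#'   data frame / list of `c(x, y)` pairs) of vertices in gaze-plane units.
#'   At least 3 vertices per polygon. Declaration order matters: when a
#'   point lies in several AOIs the first declared one wins.
#' @return A tibble with columns `name` and `polygon` (list of matrices).
#' @examples
#' aoi_set(dashboard = rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
#' @export
aoi_set <- function(...) {
  polys <- list(...)
  if (length(polys) == 0) stop_config("at least one AOI must be declared")
  if (is.null(names(polys)) || any(names(polys) == "")) {
    stop_config("every AOI polygon must be named")
  }
  polys <- purrr::map(polys, function(p) {
    if (is.data.frame(p)) p <- as.matrix(p)
    if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, p)
    p <- unname(as.matrix(p))
    if (!is.numeric(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop_config("an AOI polygon needs >= 3 numeric (x, y) vertices")
    }
    p
  })
  tibble(name = names(polys), polygon = unname(polys))
}

#' Classify gaze points into areas of interest
#'
#' Each point gets the name of the first declared AOI whose polygon contains
#' it; points on a polygon boundary count as inside; points contained by no
#' AOI get `"none"`. The first-declared-wins rule makes classification
#' deterministic when AOIs share edges or overlap.
#'
#' @param x,y Numeric vectors of gaze-plane coordinates (recycled to common
#'   length). Non-finite coordinates classify as `"none"`.
#' @param aois An [aoi_set()].
#' @return Character vector of AOI labels.
#' @export
classify_aoi <- function(x, y, aois) {
  if (!is.data.frame(aois) || nrow(aois) == 0) {
    stop_config("`aois` must be a non-empty aoi_set()")
  }
  nmax <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), nmax)
  y <- rep_len(as.numeric(y), nmax)
  out <- rep("none", nmax)
  undecided <- is.finite(x) & is.finite(y)
  for (i in seq_len(nrow(aois))) {
    if (!any(undecided)) break
    p <- aois$polygon[[i]]
    hit <- pracma::inpolygon(x[undecided], y[undecided], p[, 1], p[, 2],
                             boundary = TRUE)
    idx <- which(undecided)[hit]
    out[idx] <- aois$name[i]
    undecided[idx] <- FALSE
  }
  out
}

#' Read a gaze stream from CSV
#'
#' The file needs a header and a `t` column (seconds) plus either an `aoi`
#' column or `x`,`y` coordinates together with an AOI set to classify them.
#' An optional `valid` column flags sample quality; invalid rows are kept
#' (the detector decides how to treat them).
#'
#' @param path CSV file path.
#' @param aois Optional [aoi_set()]; required when the file has `x`,`y` but
#'   no `aoi` column.
#' @param rate_hz Optional nominal sampling rate; inferred when absent.
#' @return A [gaze_stream()].
#' @export
read_gaze_csv <- function(path, aois = NULL, rate_hz = NULL) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  # parse doubles through R's strtod (correctly rounded) rather than the
  # reader's fast float path, so files round-trip bit-exactly
  num_cols <- intersect(c("t", "x", "y"), header)
  spec <- do.call(readr::cols,
                  stats::setNames(rep(list(readr::col_character()), length(num_cols)),
                                  num_cols))
  df <- readr::read_csv(path, col_types = spec, show_col_types = FALSE,
                        progress = FALSE)
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  if (!"t" %in% names(df)) stop_format("gaze CSV must have a `t` column")
  if (!"aoi" %in% names(df)) {
    if (all(c("x", "y") %in% names(df))) {
      if (is.null(aois)) {
        stop_format("gaze CSV has x,y but no aoi column: supply `aois` to classify")
      }
      df$aoi <- classify_aoi(df$x, df$y, aois)
    } else {
      stop_format("gaze CSV must have an `aoi` column or `x` and `y` columns")
    }
  }
  gaze_stream(df, rate_hz = rate_hz)
}

#' Write a gaze stream to CSV
#' @param stream A [gaze_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(stream, path) {
  out <- as_tibble(stream)
  # 17 significant digits so doubles survive a write/read round trip exactly
  for (cl in intersect(c("t", "x", "y"), names(out))) {
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read AOI definitions from JSON
#'
#' Expects `{"aois": [{"name": ..., "polygon": [[x, y], ...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return An [aoi_set()].
#' @export
read_aois <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$aois) || length(j$aois) == 0) {
    stop_format("AOI JSON must contain a non-empty `aois` array")
  }
  polys <- purrr::map(j$aois, function(a) {
    do.call(rbind, purrr::map(a$polygon, ~ as.numeric(unlist(.x))))
  })
  names(polys) <- purrr::map_chr(j$aois, "name")
  do.call(aoi_set, polys)
}

#' Write AOI definitions to JSON
#' @param aois An [aoi_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aois <- function(aois, path) {
  out <- list(aois = purrr::map2(aois$name, aois$polygon, function(nm, p) {
    list(name = nm, polygon = purrr::map(seq_len(nrow(p)), ~ as.numeric(p[.x, ])))
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a segment annotation table
#'
#' Segments label time intervals of a drive with an experimental condition.
#' They must be well-formed (`start_s < end_s`), non-overlapping, and use
#' the [segment_conditions] vocabulary. Intervals are half-open
#' `[start_s, end_s)`, so abutting one-minute segments partition time.
#'
#' @param segments Data frame with columns `start_s`, `end_s`, `condition`.
#' @return A sorted tibble.
#' @export
segment_table <- function(segments) {
  segments <- as_tibble(segments)
  need <- c("start_s", "end_s", "condition")
  if (!all(need %in% names(segments))) {
    stop_format("segments need columns start_s, end_s, condition")
  }
  if (nrow(segments) == 0) stop_data("segment table is empty")
  segments$condition <- as.character(segments$condition)
  unknown <- setdiff(unique(segments$condition), segment_conditions)
  if (length(unknown) > 0) {
    stop_data(sprintf("unknown condition label(s): %s", toString(unknown)))
  }
  bad <- which(!(segments$start_s < segments$end_s))
  if (length(bad) > 0) {
    stop_data(sprintf("segment %d has end_s <= start_s", bad[1]))
  }
  segments <- dplyr::arrange(segments, .data$start_s)
  if (nrow(segments) > 1) {
    ov <- which(segments$start_s[-1] < segments$end_s[-nrow(segments)])
    if (length(ov) > 0) {
      stop_data(sprintf("segments %d and %d overlap", ov[1], ov[1] + 1L))
    }
  }
  segments
}

#' Read segment annotations from CSV
#' @param path CSV with columns `start_s,end_s,condition`.
#' @return A validated, sorted segment tibble (see [segment_table()]).
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  segment_table(df)
}

#' Write segment annotations to CSV
#' @param segments A segment tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  readr::write_csv(segment_table(segments), path, progress = FALSE)
  invisible(path)
}
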