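#' Write a detection stream as JSON Lines
#'
#' One JSON object per line with fields `t`, `class`, `bbox`
#' (`[x_min, y_min, x_max, y_max]`) and `conf`. Numbers are serialised
#' with 17 significant digits so a write/read round trip reproduces the
#' doubles bit-exactly.
#'
#' @param events Detection stream tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stream <- function(events, path) {
  stopifnot(is.data.frame(events))
  lines <- sprintf(
    '{"t": %.17g, "class": "%s", "bbox": [%.17g, %.17g, %.17g, %.17g], "conf": %.17g}',
    events$t, events$label, events$x_min, events$y_min,
    events$x_max, events$y_max, events$conf
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_stream_record <- function(line) {
  rec <- jsonlite::fromJSON(line)
  if (!all(c("t", "class", "bbox", "conf") %in% names(rec)) ||
      length(rec$bbox) != 4) {
    stop("missing field")
  }
  list(t = as.numeric(rec$t), class = as.character(rec$class),
       bbox = as.numeric(rec$bbox), conf = as.numeric(rec$conf))
}

#' Read a detection stream from JSON Lines
#'
#' Malformed lines are collected into a rejection report (attribute
#' `"rejections"`, with line numbers) instead of aborting the read; the
#' surviving records are then validated with [validate_stream()], whose
#' semantic rejections are appended to the report.
#'
#' @param path JSON-Lines file written by [write_stream()].
#' @param quiet Suppress the rejection-count message.
#' @return Detection stream tibble sorted by time, with attribute
#'   `"rejections"` (tibble of `row` = line number and `reason`).
#' @export
read_stream <- function(path, quiet = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- detection_stream()
    attr(out, "rejections") <- tibble::tibble(row = integer(),
                                              reason = character())
    return(out)
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                       simplifyDataFrame = TRUE, simplifyMatrix = TRUE),
    error = function(e) NULL
  )
  bad <- tibble::tibble(row = integer(), reason = character())
  bbox <- if (is.data.frame(parsed)) {
    b <- parsed$bbox
    if (is.list(b) && all(lengths(b) == 4)) b <- do.call(rbind, b)
    if (is.matrix(b) && ncol(b) == 4) b else NULL
  }
  if (is.data.frame(parsed) && !is.null(bbox) &&
      all(c("t", "class", "conf") %in% names(parsed))) {
    events <- detection_stream(
      t = parsed$t, label = parsed$class,
      x_min = bbox[, 1], y_min = bbox[, 2],
      x_max = bbox[, 3], y_max = bbox[, 4],
      conf = parsed$conf
    )
  } else {
    # slow path: per-line parse with rejection reporting
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rows[[i]] <- tryCatch(parse_stream_record(lines[i]),
                            error = function(e) NULL)
      if (is.null(rows[[i]])) {
        bad <- tibble::add_row(bad, row = line_no[i],
                               reason = "malformed JSON record")
      }
    }
    ok <- !vapply(rows, is.null, logical(1))
    rows <- rows[ok]
    line_no <- line_no[ok]
    boxes <- do.call(rbind, lapply(rows, `[[`, "bbox"))
    events <- detection_stream(
      t = vapply(rows, `[[`, 0, "t"),
      label = vapply(rows, `[[`, "", "class"),
      x_min = boxes[, 1], y_min = boxes[, 2],
      x_max = boxes[, 3], y_max = boxes[, 4],
      conf = vapply(rows, `[[`, 0, "conf")
    )
  }
  out <- validate_stream(events, quiet = TRUE)
  sem <- stream_rejections(out)
  if (nrow(sem) > 0) sem$row <- line_no[sem$row]
  rejections <- rbind(bad, sem)
  attr(out, "rejections") <- rejections
  if (!quiet && nrow(rejections) > 0) {
    message(nrow(rejections), " line(s) rejected while reading ", path)
  }
  out
}

#' Read PASCAL VOC XML annotations
#'
#' Parses the `<object><name>` and `<bndbox>` elements of a PASCAL VOC
#' annotation file. Labels are normalised (lower case, spaces/hyphens to
#' underscores) and must fall in the five-class vocabulary
#' ([event_classes()]); objects with unknown labels, missing box fields,
#' or inverted boxes are reported, not fatal. VOC boxes are inclusive
#' pixel coordinates starting at 1; they are converted to continuous
#' coordinates (`x_min = xmin - 1`, `x_max = xmax`) on load.
#'
#' @param path VOC XML file.
#' @param quiet Suppress the rejection-count message.
#' @return Tibble with columns `label`, `x_min`, `y_min`, `x_max`,
#'   `y_max`; attribute `"rejections"` lists skipped objects.
#' @export
read_voc_annotations <- function(path, quiet = FALSE) {
  doc <- xml2::read_xml(path)
  objects <- xml2::xml_find_all(doc, ".//object")
  out <- tibble::tibble(label = character(), x_min = numeric(),
                        y_min = numeric(), x_max = numeric(),
                        y_max = numeric())
  rejections <- tibble::tibble(object = integer(), reason = character())
  for (i in seq_along(objects)) {
    obj <- objects[[i]]
    raw <- xml2::xml_text(xml2::xml_find_first(obj, "./name"))
    label <- gsub("[ -]", "_", tolower(trimws(raw)))
    if (!label %in% event_classes()) {
      rejections <- tibble::add_row(rejections, object = i,
                                    reason = paste0("unknown label '", raw, "'"))
      next
    }
    box <- xml2::xml_find_first(obj, "./bndbox")
    coords <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(f) {
      node <- xml2::xml_find_first(box, paste0("./", f))
      if (inherits(node, "xml_missing")) NA_real_ else
        as.numeric(xml2::xml_text(node))
    }, 0)
    if (anyNA(coords)) {
      rejections <- tibble::add_row(rejections, object = i,
                                    reason = "missing bndbox field")
      next
    }
    x_min <- coords[["xmin"]] - 1; x_max <- coords[["xmax"]]
    y_min <- coords[["ymin"]] - 1; y_max <- coords[["ymax"]]
    if (!(x_min < x_max && y_min < y_max)) {
      rejections <- tibble::add_row(rejections, object = i,
                                    reason = "inverted or degenerate box")
      next
    }
    out <- tibble::add_row(out, label = label, x_min = x_min, y_min = y_min,
                           x_max = x_max, y_max = y_max)
  }
  attr(out, "rejections") <- rejections
  if (!quiet && nrow(rejections) > 0) {
    message(nrow(rejections), " VOC object(s) rejected while reading ", path)
  }
  out
}

#' Write / read a ground-truth script sidecar
#'
#' The simulator's ground truth (posture change points, birth times,
#' onset, litter size) serialised as JSON with full numeric precision, so
#' a simulated stream can travel with its truth.
#'
#' @param script A [simulate_sow()] script.
#' @param path JSON file.
#' @return `write_script()`: `path`, invisibly. `read_script()`: a
#'   `"sow_script"` object.
#' @export
write_script <- function(script, path) {
  stopifnot(inherits(script, "sow_script"))
  payload <- list(
    posture_path = list(t = script$posture_path$t,
                        label = as.character(script$posture_path$label)),
    birth_times = script$birth_times,
    farrow_onset = script$farrow_onset,
    litter_size = script$litter_size,
    horizon = script$horizon,
    span_seconds = script$span_seconds
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)),
             path)
  invisible(path)
}

#' @rdname write_script
#' @export
read_script <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(
    list(posture_path = tibble::tibble(
           t = as.numeric(p$posture_path$t),
           label = factor(p$posture_path$label, levels = posture_levels())),
         birth_times = as.numeric(p$birth_times),
         farrow_onset = as.numeric(p$farrow_onset),
         litter_size = as.integer(p$litter_size),
         horizon = as.numeric(p$horizon),
         span_seconds = as.numeric(p$span_seconds)),
    class = "sow_script"
  )
}

#' Export a frequency series as CSV
#'
#' Two columns, `t_hours` (window end in hours from stream start) and `f`
#' (transitions/hour).
#'
#' @param series A [frequency_series()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_frequency_series <- function(series, path) {
  stopifnot(is.data.frame(series))
  utils::write.csv(
    data.frame(t_hours = series$t / 3600, f = series$f),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a JSON report
#'
#' @param x Named list of results.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

run_config_keys <- function() {
  list(
    warning = names(formals(warning_config)),
    monitor = names(formals(monitor_config)),
    profile = names(formals(behavior_profile)),
    litter = names(formals(litter_model)),
    noise = names(formals(noise_profile)),
    top = c("seed", "frame_interval", "stream_start_iso", "noise_scenario")
  )
}

#' Read a run configuration
#'
#' YAML file with optional sections `warning`, `monitor`, `profile`,
#' `litter`, `noise` (each holding the corresponding constructor's
#' arguments) plus top-level `seed`, `frame_interval`, `stream_start_iso`
#' and `noise_scenario`. Unknown sections or keys are rejected with the
#' offending key named.
#'
#' @param path YAML file.
#' @return A list with elements `warning` ([warning_config()]), `monitor`
#'   ([monitor_config()]), `profile` ([behavior_profile()]), `litter`
#'   ([litter_model()]), `noise` ([noise_profile()]), `seed`,
#'   `frame_interval`, `stream_start_iso`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  keys <- run_config_keys()
  known_sections <- c("warning", "monitor", "profile", "litter", "noise")
  unknown <- setdiff(names(raw), c(known_sections, keys$top))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(section, constructor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), keys[[section]])
    if (length(bad) > 0) {
      stop("unknown config key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    }
    do.call(constructor, args)
  }
  noise <- if (!is.null(raw$noise_scenario)) {
    presets <- noise_presets()
    if (!raw$noise_scenario %in% names(presets)) {
      stop("unknown noise_scenario '", raw$noise_scenario, "'")
    }
    presets[[raw$noise_scenario]]
  } else {
    build("noise", noise_profile)
  }
  list(
    warning = build("warning", warning_config),
    monitor = build("monitor", monitor_config),
    profile = build("profile", behavior_profile),
    litter = build("litter", litter_model),
    noise = noise,
    seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
    frame_interval = if (is.null(raw$frame_interval)) 1 else
      as.numeric(raw$frame_interval),
    stream_start_iso = raw$stream_start_iso
  )
}
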