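#' Write a results table to CSV
#'
#' Writes per-peak or per-response records as a CSV with a header and a
#' deterministic column order (the schema of the first record). All
#' records must share the same schema. Numeric fields are serialized
#' with 17 significant digits so that re-reading reproduces the exact
#' double values.
#'
#' @param records A data.frame, or a list of named lists/vectors
#'   sharing the same field names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) == 0) {
      stop("cannot infer a schema from an empty record list; ",
           "pass a data.frame with the desired columns", call. = FALSE)
    }
    schema <- names(records[[1]])
    if (is.null(schema) || any(!nzchar(schema))) {
      stop("records must have named fields", call. = FALSE)
    }
    for (r in records) {
      if (!identical(sort(names(r)), sort(schema))) {
        stop("records do not share a common schema", call. = FALSE)
      }
    }
    df <- do.call(rbind, lapply(records, function(r) {
      as.data.frame(as.list(r)[schema], stringsAsFactors = FALSE)
    }))
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Render a response map as a PNG heat map with a numeric sidecar
#'
#' The PNG uses a fixed color scale (default 0--15 % change, matching
#' the convention that dark colors mean little or no perfusion change
#' and the top of the scale a 15 % increase). Pixels flagged missing
#' (`NA`, e.g. outside the ROI) are drawn in neutral gray. A lossless
#' numeric export (`<path>.csv`, the full-precision matrix) is written
#' alongside; `NaN`/`Inf` values are rejected with the index of the
#' first offending pixel.
#'
#' @param map Numeric matrix of percent changes (typically 120 x 120).
#' @param path Output PNG path.
#' @param scale Length-2 numeric, color-scale limits in percent.
#' @param palette Name of an [grDevices::hcl.colors()] palette.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(map, path, scale = c(0, 15), palette = "Viridis") {
  stopifnot(is.matrix(map), length(scale) == 2, scale[2] > scale[1])
  bad <- which(is.nan(map) | is.infinite(map))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(map))
    stop(sprintf("map contains a non-finite value at pixel (%d, %d)",
                 idx[1], idx[2]), call. = FALSE)
  }
  ncol_pal <- 256L
  pal <- grDevices::hcl.colors(ncol_pal, palette)
  z <- (map - scale[1]) / (scale[2] - scale[1])
  z <- pmin(pmax(z, 0), 1)
  ki <- matrix(1L + as.integer(round(z * (ncol_pal - 1))), nrow(map))
  rgb <- grDevices::col2rgb(pal) / 255
  img <- array(0.5, c(nrow(map), ncol(map), 3))  # gray for missing
  ok <- !is.na(ki)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ok] <- rgb[ch, ki[ok]]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  num_path <- paste0(path, ".csv")
  write_matrix_csv(unclass(map), num_path)
  invisible(path)
}

#' Write / read a plain numeric matrix as CSV at full precision
#'
#' @param m Numeric matrix (`NA` allowed).
#' @param path CSV path.
#' @return For the reader, the matrix; for the writer, `path`
#'   invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  rows <- apply(m, 1, function(r) {
    v <- sprintf("%.17g", r)
    v[is.na(r)] <- "NA"
    paste(v, collapse = ",")
  })
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  rows <- readLines(path)
  do.call(rbind, lapply(strsplit(rows, ","), function(v) {
    v[v == "NA"] <- NA_character_
    as.numeric(v)
  }))
}

#' Read / write stimulation event markers
#'
#' Markers give externally known stimulus periods (for example the
#' 5-min CO2 inhalation window defined by the capnograph) as labeled
#' `[start_s, end_s)` intervals in a JSON file:
#' `[{"label": "co2", "start_s": 120, "end_s": 420}, ...]`.
#' Intervals must be well-ordered and non-overlapping per label.
#'
#' @param path JSON file path.
#' @return A data.frame with columns `label`, `start_s`, `end_s`.
#' @export
read_event_markers <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(ev)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(ev))) {
    stop("marker file must contain fields label, start_s, end_s",
         call. = FALSE)
  }
  validate_event_markers(ev)
  ev[, need]
}

#' @rdname read_event_markers
#' @param events Data.frame of events to write.
#' @export
write_event_markers <- function(events, path) {
  validate_event_markers(events)
  jsonlite::write_json(events, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_event_markers <- function(ev) {
  if (any(!(ev$start_s < ev$end_s))) {
    stop("event markers must satisfy start_s < end_s", call. = FALSE)
  }
  for (lb in unique(ev$label)) {
    e <- ev[ev$label == lb, ]
    e <- e[order(e$start_s), ]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)])) {
      stop("event markers overlap for label '", lb, "'", call. = FALSE)
    }
  }
  invisible(ev)
}

#' Read vessel measurement lines from a JSON file
#'
#' The declarative replacement for interactive line drawing: a JSON
#' array of objects with endpoints in pixel coordinates (row, col),
#' a label, a vessel class and optionally a line thickness, e.g.
#' `[{"label": "cap1", "class": "capillary", "p0": [10, 40],
#' "p1": [90, 40], "thickness_voxels": 4}]`.
#'
#' @param path JSON file path.
#' @return A list of [measurement_line()] objects.
#' @export
read_measurement_lines <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(raw)) stop("no measurement lines in ", path, call. = FALSE)
  lapply(seq_along(raw), function(i) {
    ln <- raw[[i]]
    if (is.null(ln$p0) || is.null(ln$p1)) {
      stop("measurement line ", i, " lacks p0/p1 endpoints", call. = FALSE)
    }
    measurement_line(
      p0 = as.numeric(unlist(ln$p0)), p1 = as.numeric(unlist(ln$p1)),
      thickness_voxels = if (is.null(ln$thickness_voxels)) 4L
                         else as.integer(ln$thickness_voxels),
      label = if (is.null(ln$label)) paste0("line", i) else ln$label,
      vessel_class = if (is.null(ln$class)) NA_character_ else ln$class,
      color_id = if (is.null(ln$color_id)) i else as.integer(ln$color_id))
  })
}

#' A vessel measurement line
#'
#' A straight segment drawn across a vessel, measured together with
#' `thickness_voxels` parallel lines (default 4, offset symmetrically
#' perpendicular to the segment at unit spacing) whose diameters are
#' averaged. Averaging over parallel lines damps the diameter
#' underestimation caused by passing erythrocytes that darken single
#' voxels.
#'
#' @param p0,p1 Numeric length-2 endpoints `(row, col)` in pixel
#'   coordinates; must differ.
#' @param thickness_voxels Number of parallel lines averaged (>= 1).
#' @param label Free-text identifier.
#' @param vessel_class One of `"pial"`, `"penetrating"`, `"capillary"`
#'   or `NA`.
#' @param color_id Integer used to pair overlay and trace colors.
#' @return A list of class `"measurement_line"`.
#' @export
measurement_line <- function(p0, p1, thickness_voxels = 4L,
                             label = "line", vessel_class = NA_character_,
                             color_id = 1L) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 2, length(p1) == 2)
  if (all(p0 == p1)) stop("line endpoints must differ", call. = FALSE)
  if (thickness_voxels < 1) stop("thickness_voxels must be >= 1",
                                 call. = FALSE)
  if (!is.na(vessel_class) &&
      !vessel_class %in% c("pial", "penetrating", "capillary")) {
    stop("vessel_class must be pial, penetrating or capillary",
         call. = FALSE)
  }
  structure(list(p0 = p0, p1 = p1,
                 thickness_voxels = as.integer(thickness_voxels),
                 label = label, vessel_class = vessel_class,
                 color_id = as.integer(color_id)),
            class = "measurement_line")
}
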