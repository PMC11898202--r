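#' Read YOLO-OBB text labels or detections
#'
#' Each non-empty line is `class x1 y1 x2 y2 x3 y3 x4 y4 [conf]` with class
#' index 0 = left ear root, 1 = right ear root. Two coordinate dialects are
#' supported: `"normalized"` (the YOLO ecosystem convention, coordinates in
#' \[0, 1\] scaled by the frame dimensions) and `"pixel"` (absolute pixel
#' coordinates). Vertices are canonicalized on read.
#'
#' @param path Path to the TXT file.
#' @param dialect `"normalized"` (default) or `"pixel"`.
#' @param frame_shape `c(rows, cols)`; required for the normalized dialect.
#' @param frame Frame identifier; defaults to the file name without extension.
#' @return A box tibble (see [obb-tables]); zero rows for an empty file.
#' @export
read_obb_txt <- function(path, dialect = c("normalized", "pixel"),
                         frame_shape = NULL, frame = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "normalized" && is.null(frame_shape)) {
    stop("frame_shape is required for the normalized dialect", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(frame)) frame <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(obb_table(list(), character(0), frame = character(0)))
  }
  parse_line <- function(ln) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (!length(toks) %in% c(9L, 10L)) {
      stop(sprintf("line %d: expected 9 or 10 tokens, got %d", ln,
                   length(toks)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric token", ln), call. = FALSE)
    }
    if (!vals[1] %in% c(0, 1)) {
      stop(sprintf("line %d: class index must be 0 or 1", ln), call. = FALSE)
    }
    v <- matrix(vals[2:9], ncol = 2, byrow = TRUE)
    if (dialect == "normalized") {
      v[, 1] <- v[, 1] * frame_shape[2]
      v[, 2] <- v[, 2] * frame_shape[1]
    }
    v <- tryCatch(canonicalize_vertices(v), error = function(e) {
      stop(sprintf("line %d: %s", ln, conditionMessage(e)), call. = FALSE)
    })
    list(class = if (vals[1] == 0) "left" else "right", v = v,
         conf = if (length(vals) == 10) vals[10] else NA_real_)
  }
  recs <- lapply(keep, parse_line)
  obb_table(lapply(recs, `[[`, "v"),
            class = vapply(recs, `[[`, character(1), "class"),
            frame = frame,
            conf = vapply(recs, `[[`, numeric(1), "conf"))
}

#' Write a box table in YOLO-OBB text format
#'
#' Mirrors [read_obb_txt()] exactly; detection rows (non-`NA` `conf`) get the
#' confidence appended as a tenth token. Coordinates are written with enough
#' digits for a lossless (sub-1e-6 pixel) round trip.
#'
#' @param boxes A box tibble.
#' @param path Output path.
#' @param dialect `"normalized"` (default) or `"pixel"`.
#' @param frame_shape `c(rows, cols)`; required for the normalized dialect.
#' @return `path`, invisibly.
#' @export
write_obb_txt <- function(boxes, path, dialect = c("normalized", "pixel"),
                          frame_shape = NULL) {
  dialect <- match.arg(dialect)
  .validate_boxes(boxes)
  if (dialect == "normalized" && is.null(frame_shape)) {
    stop("frame_shape is required for the normalized dialect", call. = FALSE)
  }
  lines <- vapply(seq_len(nrow(boxes)), function(i) {
    v <- obb_vertices(boxes, i)
    if (dialect == "normalized") {
      v[, 1] <- v[, 1] / frame_shape[2]
      v[, 2] <- v[, 2] / frame_shape[1]
      fmt <- "%.12f"
    } else {
      fmt <- "%.8f"
    }
    toks <- c(if (boxes$class[i] == "left") "0" else "1",
              sprintf(fmt, as.vector(t(v))))
    if (!is.na(boxes$conf[i])) toks <- c(toks, sprintf("%.6f", boxes$conf[i]))
    paste(toks, collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert roLabelImg rotated-box XML annotations to a box table
#'
#' roLabelImg stores each rotated box as center `(cx, cy)`, size `(w, h)` and
#' a rotation `angle` in radians, clockwise in the image frame. Labels
#' `"Left ear root"` and `"Right ear root"` (case-insensitive) map to classes
#' left and right.
#'
#' @param xml_path Path to the XML file.
#' @param frame Frame identifier; defaults to the file name.
#' @return A box tibble.
#' @export
read_rolabelimg <- function(xml_path, frame = NULL) {
  if (is.null(frame)) frame <- sub("\\.[^.]*$", "", basename(xml_path))
  doc <- xml2::read_xml(xml_path)
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0) {
    return(obb_table(list(), character(0), frame = character(0)))
  }
  num <- function(node, what) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, what)))
  }
  recs <- lapply(objs, function(o) {
    lab <- tolower(trimws(xml2::xml_text(xml2::xml_find_first(o, ".//name"))))
    cls <- switch(lab, "left ear root" = "left", "right ear root" = "right",
                  stop("unknown label string: ", lab, call. = FALSE))
    v <- rotated_rect(num(o, ".//robndbox/cx"), num(o, ".//robndbox/cy"),
                      num(o, ".//robndbox/w"), num(o, ".//robndbox/h"),
                      num(o, ".//robndbox/angle"))
    list(class = cls, v = v)
  })
  obb_table(lapply(recs, `[[`, "v"),
            class = vapply(recs, `[[`, character(1), "class"),
            frame = frame)
}

#' Thermal frames
#'
#' A `thermal_frame` is an 8-bit grayscale pixel matrix together with the
#' frame's minimum and maximum temperature in degrees Celsius; the linear
#' map between gray levels and temperature is [gray_to_temp()]. 8-bit
#' PNG/TIFF images cannot carry a radiometric scale, so `t_min`/`t_max`
#' travel in a JSON sidecar (`{"t_min": ..., "t_max": ...}`).
#'
#' @param pixels Integer matrix (rows x cols) of gray levels in \[0, 255\].
#' @param t_min,t_max Frame temperature extrema in degrees C, `t_max > t_min`.
#' @param id Frame identifier.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(pixels, t_min, t_max, id = "frame") {
  pixels <- round(pixels)
  if (!is.matrix(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stop("pixels must be a matrix of gray levels in [0, 255]", call. = FALSE)
  }
  if (!is.finite(t_min) || !is.finite(t_max) || t_max <= t_min) {
    stop("t_max must exceed t_min", call. = FALSE)
  }
  structure(list(pixels = pixels, t_min = as.numeric(t_min),
                 t_max = as.numeric(t_max), id = as.character(id)),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame %s: %d x %d px, %.2f to %.2f degC>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$t_min, x$t_max))
  invisible(x)
}

#' Read a thermal frame and its temperature sidecar
#'
#' @param image_path 8-bit single-channel PNG or TIFF.
#' @param meta_path JSON sidecar with `t_min` and `t_max` in degrees C;
#'   defaults to the image path with a `.json` extension.
#' @return A [thermal_frame()].
#' @export
read_thermal_frame <- function(image_path,
                               meta_path = sub("\\.[^.]*$", ".json",
                                               image_path)) {
  if (!file.exists(image_path)) {
    stop("image not found: ", image_path, call. = FALSE)
  }
  if (!file.exists(meta_path)) {
    stop("temperature sidecar not found: ", meta_path, call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", image_path))
  img <- switch(ext,
    png = png::readPNG(image_path),
    tif = ,
    tiff = tiff::readTIFF(image_path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) != 2) {
    stop("expected a single-channel grayscale image", call. = FALSE)
  }
  px <- img * 255
  if (max(abs(px - round(px))) > 1e-6) {
    stop("expected an 8-bit image (gray levels not integral)", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$t_min) || is.null(meta$t_max)) {
    stop("sidecar must provide t_min and t_max", call. = FALSE)
  }
  thermal_frame(round(px), meta$t_min, meta$t_max,
                id = sub("\\.[^.]*$", "", basename(image_path)))
}

#' Write a thermal frame and its temperature sidecar
#'
#' @param frame A [thermal_frame()].
#' @param image_path Output PNG path.
#' @param meta_path Output JSON sidecar path; defaults alongside the image.
#' @return `image_path`, invisibly.
#' @export
write_thermal_frame <- function(frame, image_path,
                                meta_path = sub("\\.[^.]*$", ".json",
                                                image_path)) {
  png::writePNG(frame$pixels / 255, image_path)
  jsonlite::write_json(list(t_min = frame$t_min, t_max = frame$t_max),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}
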