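#' Run the per-frame pairing and temperature pipeline over a dataset
#'
#' For every frame: read the thermal image and its temperature sidecar, read
#' the detections (or ground-truth labels), run two-stage pairing, and
#' extract per-pig ear-root temperatures. Frames with missing or malformed
#' inputs are skipped with a warning and listed in the summary; the call
#' fails only if every frame fails.
#'
#' @param frames Character vector of image paths, or a directory containing
#'   `*.png` frames with `.json` sidecars and `.txt` label files sharing the
#'   image stem (the layout written by [generate_dataset()]).
#' @param labels Optional character vector of label TXT paths, parallel to
#'   `frames`; derived from the image stems when `frames` is a directory.
#' @param config A [pairing_config()].
#' @param dialect Label TXT dialect (see [read_obb_txt()]).
#' @param out_dir Optional output directory; when given, `pairs.csv`,
#'   `temperatures.csv` and `summary.json` are written there.
#' @return List with `pairs` (all frames' pair tables), `temperatures`,
#'   `unpaired`, and `summary` (frame/pair/temperature counts by stage).
#' @export
run_pipeline <- function(frames, labels = NULL, config = pairing_config(),
                         dialect = "normalized", out_dir = NULL) {
  if (length(frames) == 1 && dir.exists(frames)) {
    frames <- sort(list.files(frames, pattern = "\\.png$",
                              full.names = TRUE))
  }
  if (length(frames) == 0) stop("no frames to process", call. = FALSE)
  if (is.null(labels)) labels <- sub("\\.png$", ".txt", frames)
  stopifnot(length(labels) == length(frames))

  failed <- character(0)
  pair_tabs <- list(); temp_tabs <- list(); unpaired_tabs <- list()
  for (i in seq_along(frames)) {
    stem <- sub("\\.[^.]*$", "", basename(frames[i]))
    res <- tryCatch({
      fr <- read_thermal_frame(frames[i])
      boxes <- read_obb_txt(labels[i], dialect = dialect,
                            frame_shape = dim(fr$pixels), frame = stem)
      pairing <- pair_ears(boxes, config)
      temps <- pig_temperature(fr, pairing)
      list(pairs = dplyr::mutate(pairing$pairs, frame = stem, .before = 1),
           temps = dplyr::mutate(temps, frame = stem, .before = 1),
           unpaired = pairing$unpaired)
    }, error = function(e) {
      warning(sprintf("frame %s skipped: %s", stem, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) { failed <- c(failed, stem); next }
    pair_tabs[[stem]] <- res$pairs
    temp_tabs[[stem]] <- res$temps
    unpaired_tabs[[stem]] <- res$unpaired
  }
  if (length(pair_tabs) == 0 && length(failed) > 0) {
    stop("all frames failed: ", paste(failed, collapse = ", "),
         call. = FALSE)
  }
  pairs <- dplyr::bind_rows(pair_tabs)
  temps <- dplyr::bind_rows(temp_tabs)
  unpaired <- dplyr::bind_rows(unpaired_tabs)
  summary <- list(
    n_frames = length(frames), n_failed = length(failed),
    failed_frames = failed,
    n_pairs = nrow(pairs),
    pairs_by_stage = as.list(table(pairs$stage)),
    n_unpaired = nrow(unpaired),
    n_temperature_records = nrow(temps),
    t_pig_mean = if (nrow(temps) > 0) mean(temps$t_pig, na.rm = TRUE)
                 else NA,
    t_pig_range = if (nrow(temps) > 0) range(temps$t_pig, na.rm = TRUE)
                  else NA)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
    write.csv(temps, file.path(out_dir, "temperatures.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pairs = pairs, temperatures = temps, unpaired = unpaired,
       summary = summary)
}
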