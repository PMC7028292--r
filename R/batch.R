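#' Batch analysis runs
#'
#' Processes a list of images independently with one shared configuration,
#' writing a per-image result row keyed by content [image_id()], a combined
#' summary CSV, and a JSON run manifest (configuration, image IDs, package
#' version) beside the outputs.  A failing image is recorded and the
#' remaining images are still processed.
#'
#' @param config a named list (or path to a YAML/JSON file) with at least
#'   `analysis` (`"classify"`, `"segment"` or `"fibres"`) and the
#'   analysis-specific entries: `model` (path to a saved pixel classifier)
#'   for classify/segment, `fibre` parameter list for fibres,
#'   `annotations` (path) optionally for all, `seed`, `workers`, `out_dir`.
#' @param images character vector of image paths, or a list of
#'   [tiled_image] objects (overrides `config$images`).
#' @return `list(summary, failures)`; `summary` is a data.frame with one row
#'   per successfully processed image.
#' @export
run_batch <- function(config, images = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$analysis))
    stop("invalid config: `analysis` is required")
  if (!config$analysis %in% c("classify", "segment", "fibres"))
    stop("invalid config: unknown analysis '", config$analysis, "'")
  images <- images %||% config$images
  if (is.null(images) || !length(images)) stop("invalid config: no images")
  workers <- config$workers %||% 1L
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (!is.null(config$model)) load_pixel_classifier(config$model)
  annots <- if (!is.null(config$annotations)) read_annotations(config$annotations)
  rows <- list(); failures <- list()
  for (i in seq_along(images)) {
    name <- if (is.character(images)) images[[i]] else sprintf("image_%d", i)
    res <- tryCatch({
      img <- if (is.character(images)) read_wsi(images[[i]]) else images[[i]]
      id <- image_id(img)
      d <- image_dim(img, 0L)
      roi <- if (!is.null(annots))
        effective_roi(annots, d[[1]], d[[2]]) else NULL
      row <- switch(config$analysis,
        classify = {
          r <- classify_image(model, img, roi = roi, workers = workers)
          out <- data.frame(image_id = id, t(r$ratios), roi_area = r$roi_area,
                            check.names = FALSE)
          names(out)[2:(1 + length(r$ratios))] <-
            paste0("ratio_", names(r$counts))
          out
        },
        segment = {
          sp <- do.call(segmentation_params, config$segmentation %||% list())
          objs <- segment_objects(img, model, sp, roi = roi,
                                  foreground_classes =
                                    config$foreground_classes,
                                  workers = workers)
          data.frame(image_id = id, n_objects = length(objs))
        },
        fibres = {
          fp <- do.call(fibre_params, config$fibre %||% list())
          fb <- trace_fibres(img, fp, roi = roi, workers = workers)
          row <- data.frame(image_id = id, n_fibres = length(fb))
          junction <- if (!is.null(annots))
            Filter(function(a) a$type == "junction_line", annots)
          if (length(junction)) {
            cr <- count_junction_crossings(fb, junction[[1]], d = fp$d,
                                           pixel_size = config$pixel_size)
            row$crossings <- cr$total
            row$density <- cr$density
          }
          row
        })
      row$source <- name
      row
    }, error = function(e) {
      structure(list(source = name, message = conditionMessage(e)),
                class = "batch_failure")
    })
    if (inherits(res, "batch_failure")) failures[[length(failures) + 1L]] <- res
    else rows[[length(rows) + 1L]] <- res
  }
  summary <- if (length(rows)) do.call(rbind, rows) else data.frame()
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    config = config[setdiff(names(config), "images")],
    analysis = config$analysis,
    image_ids = if (nrow(summary)) summary$image_id else character(0),
    failures = lapply(failures, function(f)
      list(source = f$source, message = f$message)),
    package_version = as.character(utils::packageVersion("tilescope")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(summary = summary, failures = failures)
}
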