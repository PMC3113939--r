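## Batch orchestration: discover image jobs from filenames, run the
## calibrated analysis per image, and emit the result table plus optional
## annotated images and processing-stage stacks.

RESULT_COLUMNS <- c("plant_id", "view", "timepoint",
                    "x_extent_mm", "y_extent_mm", "diameter_mm",
                    "width_mm", "height_mm", "projected_shoot_area_mm2",
                    "pixel_count", "empty_flag",
                    "source_path", "config_id", "software_version")

.templateRegex <- function(pattern) {
  fields <- c("plant_id", "view", "timepoint")
  pos <- vapply(fields, function(f)
    as.integer(regexpr(paste0("{", f, "}"), pattern, fixed = TRUE)),
    integer(1))
  if (any(pos < 0L))
    stop("'pattern' must contain {plant_id}, {view} and {timepoint}")
  fieldOrder <- fields[order(pos)]
  ## split into literal chunks around the placeholders, escape the literals
  ## (PCRE: backslash before any non-alphanumeric is a literal match)
  marked <- pattern
  for (f in fields)
    marked <- sub(paste0("{", f, "}"), "\001", marked, fixed = TRUE)
  parts <- strsplit(marked, "\001", fixed = TRUE)[[1L]]
  while (length(parts) < length(fields) + 1L) parts <- c(parts, "")
  esc <- function(s) gsub("([^A-Za-z0-9_])", "\\\\\\1", s)
  rx <- paste0("^", paste0(vapply(parts, esc, character(1)),
                           collapse = "([^_/]+)"), "$")
  list(rx = rx, order = fieldOrder)
}

#' Discover image jobs in a directory
#'
#' Matches the files of a directory against a filename template with the
#' named fields `{plant_id}`, `{view}` and `{timepoint}` (field values may
#' not contain underscores).  Files that do not match the template, or whose
#' view field is not `top`/`side`, are skipped with a warning.  Jobs are
#' returned in deterministic lexicographic filename order.
#'
#' @param root directory to scan.
#' @param pattern filename template, e.g.
#'   `"{plant_id}_{view}_d{timepoint}.png"`.
#' @return A `data.frame` of jobs with columns `path`, `plant_id`, `view`,
#'   `timepoint`.
#' @seealso [runBatch()]
#' @export
discoverJobs <- function(root, pattern = "{plant_id}_{view}_{timepoint}.png") {
  if (!dir.exists(root)) stop("directory does not exist: ", root)
  tpl <- .templateRegex(pattern)
  files <- sort(list.files(root), method = "radix")
  jobs <- list(); skipped <- character()
  for (f in files) {
    mm <- regmatches(f, regexec(tpl$rx, f, perl = TRUE))[[1L]]
    if (length(mm) != 4L) { skipped <- c(skipped, f); next }
    vals <- stats::setNames(mm[-1L], tpl$order)
    if (!vals[["view"]] %in% c("top", "side")) { skipped <- c(skipped, f); next }
    jobs[[length(jobs) + 1L]] <- data.frame(
      path = file.path(root, f), plant_id = vals[["plant_id"]],
      view = vals[["view"]], timepoint = vals[["timepoint"]],
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " file(s) not matching the template: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
  if (!length(jobs))
    return(data.frame(path = character(), plant_id = character(),
                      view = character(), timepoint = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, jobs)
}

#' Analyse a single plant image
#'
#' The per-image pipeline: segment by MHT, extract the plant, refine it by
#' morphological opening (radius from the configuration), and measure.
#' Optionally renders every processing stage for the image stack.
#'
#' @param img an image array or a file path.
#' @param cfg the [ViewConfig] for the image's view.
#' @param plantId,timepoint identifiers for the record.
#' @param keepStages also return the six stage images (original, regions
#'   overlay, colour-coded labels, extracted plant, opened plant, annotated
#'   result)?
#' @param style [annotationStyle()] used for the annotated result.
#' @return A list with elements `record` ([measurePlant()] row), `labels`
#'   ([LabelImage]), `mask` (raw [PlantMask]), `opened` (refined mask),
#'   `annotated` (image array) and, if requested, `stages` (list of 6
#'   arrays).
#' @export
analyseImage <- function(img, cfg, plantId = "plant", timepoint = "",
                         keepStages = FALSE, style = annotationStyle()) {
  if (is.character(img)) img <- readPlantImage(img)
  li <- segmentImage(img, cfg)
  pm <- extractPlant(li)
  opened <- maskOpening(pm, openingRadius(cfg))
  rec <- measurePlant(opened, cfg, plantId, timepoint)
  ann <- renderAnnotation(img, opened, rec, style, cfg@mmPerPx)
  out <- list(record = rec, labels = li, mask = pm, opened = opened,
              annotated = ann)
  if (keepStages) {
    maskImg <- function(m) {
      a <- array(0L, dim = c(dim(m@mask), 3L))
      for (k in 1:3) a[, , k] <- m@mask * 255L
      a
    }
    out$stages <- list(original = img,
                       regions = regionOverlayImage(img, cfg),
                       labels = labelColourImage(li, cfg),
                       extracted = maskImg(pm),
                       opened = maskImg(opened),
                       annotated = ann)
  }
  out
}

#' Run a batch of image jobs
#'
#' Processes every job with the configuration of its view and collects one
#' measurement row per successfully processed image, in input order.
#' Failures are logged and reported in the `failures` attribute without
#' aborting the batch.  Given identical inputs and configurations the run is
#' deterministic.
#'
#' @param jobs a jobs `data.frame` from [discoverJobs()] (columns `path`,
#'   `plant_id`, `view`, `timepoint`).
#' @param configs named list of [ViewConfig]s keyed by view (`top`, `side`);
#'   a missing configuration for a requested view is an error raised before
#'   any processing starts.
#' @param outDir optional output directory for annotated images and stacks.
#' @param annotate write `<plant>_<view>_<timepoint>_annotated.png` per job?
#' @param stacks write a per-job multi-page processing-stage TIFF?
#' @param style [annotationStyle()] for the overlays.
#' @return The result table: a `data.frame` with the measurement columns
#'   plus provenance (`source_path`, `config_id`, `software_version`), one
#'   row per success, with a `data.frame` of failures (columns `path`,
#'   `error`) in `attr(, "failures")`.
#' @seealso [writeResultTable()], [summarizeGroups()]
#' @export
runBatch <- function(jobs, configs, outDir = NULL, annotate = FALSE,
                     stacks = FALSE, style = annotationStyle()) {
  need <- unique(jobs$view)
  missing <- setdiff(need, names(configs))
  if (length(missing))
    stop("no configuration for view(s): ", paste(missing, collapse = ", "))
  if ((annotate || stacks) && is.null(outDir))
    stop("'outDir' is required when annotate or stacks are enabled")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (annotate) dir.create(file.path(outDir, "annotated"),
                             showWarnings = FALSE)
    if (stacks) dir.create(file.path(outDir, "stacks"), showWarnings = FALSE)
  }
  version <- as.character(utils::packageVersion("phenopipe"))
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(jobs))) {
    job <- jobs[i, ]
    cfg <- configs[[job$view]]
    res <- tryCatch({
      ana <- analyseImage(job$path, cfg, job$plant_id, job$timepoint,
                          keepStages = stacks, style = style)
      stem <- sprintf("%s_%s_%s", job$plant_id, job$view, job$timepoint)
      if (annotate)
        writePlantImage(ana$annotated,
                        file.path(outDir, "annotated",
                                  paste0(stem, "_annotated.png")))
      if (stacks)
        buildStack(ana$stages,
                   file.path(outDir, "stacks", paste0(stem, "_stack.tif")))
      rec <- ana$record
      rec$source_path <- job$path
      rec$config_id <- cfg@configId
      rec$software_version <- version
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("job failed: ", job$path, " (", conditionMessage(res), ")")
      fails[[length(fails) + 1L]] <- data.frame(
        path = job$path, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(nrow = 0L, ncol = length(RESULT_COLUMNS))),
      RESULT_COLUMNS)
  tab <- tab[, RESULT_COLUMNS]
  rownames(tab) <- NULL
  attr(tab, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(path = character(), error = character(),
               stringsAsFactors = FALSE)
  tab
}

.fmtNum <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the result table as CSV
#'
#' UTF-8 comma-separated export with a fixed, documented column order
#' (`plant_id, view, timepoint, x_extent_mm, y_extent_mm, diameter_mm,
#' width_mm, height_mm, projected_shoot_area_mm2, pixel_count, empty_flag,
#' source_path, config_id, software_version`).  Lengths are written with 2
#' decimal places, areas with 1; parameters of the other view are empty
#' fields.  The formatting is fixed so that re-running an identical batch
#' reproduces the file byte for byte.
#'
#' @param tab a result table from [runBatch()] (or [measurePlant()] rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readResultTable()]
#' @export
writeResultTable <- function(tab, path) {
  for (cc in setdiff(RESULT_COLUMNS, names(tab))) tab[[cc]] <- NA
  lines <- paste(RESULT_COLUMNS, collapse = ",")
  if (nrow(tab)) {
    body <- data.frame(
      plant_id = as.character(tab$plant_id), view = as.character(tab$view),
      timepoint = as.character(tab$timepoint),
      x_extent_mm = .fmtNum(tab$x_extent_mm, 2L),
      y_extent_mm = .fmtNum(tab$y_extent_mm, 2L),
      diameter_mm = .fmtNum(tab$diameter_mm, 2L),
      width_mm = .fmtNum(tab$width_mm, 2L),
      height_mm = .fmtNum(tab$height_mm, 2L),
      projected_shoot_area_mm2 = .fmtNum(tab$projected_shoot_area_mm2, 1L),
      pixel_count = as.character(tab$pixel_count),
      empty_flag = ifelse(tab$empty_flag, "TRUE", "FALSE"),
      source_path = as.character(tab$source_path),
      config_id = as.character(tab$config_id),
      software_version = as.character(tab$software_version),
      stringsAsFactors = FALSE)
    body[is.na(body)] <- ""
    lines <- c(lines, do.call(paste, c(unname(as.list(body)), sep = ",")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a result table CSV
#'
#' Parses a CSV written by [writeResultTable()] back into a `data.frame`
#' with numeric measurement columns.
#'
#' @param path CSV path.
#' @return A `data.frame` in the documented column order.
#' @export
readResultTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(plant_id = "character", view = "character",
                                 timepoint = "character",
                                 source_path = "character",
                                 config_id = "character",
                                 software_version = "character"))
}
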