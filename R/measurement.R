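## Phenotypic parameters from the refined plant mask: x/y-extent and maximum
## Feret diameter in top view, width and height in side view, projected shoot
## area in both.  All extents use the inclusive pixel-count convention
## (max - min + 1): a single pixel is one pixel wide.  Measurements are taken
## after the morphological opening.

.truePixelXY <- function(m) {
  idx <- which(m@mask, arr.ind = TRUE)
  ## 0-based pixel-centre coordinates: x = column, y = row
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

#' Axis-aligned extents of a plant mask
#'
#' @param m a [PlantMask].
#' @return Named numeric vector `c(x_extent, y_extent)` in pixels, using the
#'   inclusive convention `max - min + 1`; `c(0, 0)` for an empty mask.
#' @examples
#' m <- PlantMask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
#' maskExtents(m)  # single pixel: (1, 1)
#' @export
maskExtents <- function(m) {
  if (!any(m@mask)) return(c(x_extent = 0, y_extent = 0))
  xy <- .truePixelXY(m)
  c(x_extent = max(xy[, "x"]) - min(xy[, "x"]) + 1,
    y_extent = max(xy[, "y"]) - min(xy[, "y"]) + 1)
}

#' Width and height of a plant mask (side view)
#'
#' Identical computation to [maskExtents()], reported under the side-view
#' parameter names: width is the horizontal extent, height the vertical one.
#'
#' @param m a [PlantMask].
#' @return Named numeric vector `c(width, height)` in pixels.
#' @export
maskWidthHeight <- function(m) {
  e <- maskExtents(m)
  c(width = unname(e["x_extent"]), height = unname(e["y_extent"]))
}

.feret <- function(m) {
  if (!any(m@mask)) return(list(d = 0, ends = NULL))
  xy <- .truePixelXY(m)
  if (nrow(xy) == 1L) return(list(d = 0, ends = rbind(xy[1L, ], xy[1L, ])))
  hull <- grDevices::chull(xy[, "x"], xy[, "y"])
  pts <- xy[hull, , drop = FALSE]
  if (nrow(pts) == 1L) return(list(d = 0, ends = rbind(pts[1L, ], pts[1L, ])))
  dd <- as.matrix(stats::dist(pts))
  k <- which(dd == max(dd), arr.ind = TRUE)[1L, ]
  list(d = max(dd), ends = pts[c(k[1L], k[2L]), , drop = FALSE])
}

#' Maximum Feret diameter of a plant mask (top view)
#'
#' The plant "diameter" is taken as the maximum Feret diameter: the largest
#' Euclidean distance between the centres of any two plant pixels.  Computed
#' via the convex hull of the pixel centres ([grDevices::chull()]) — the
#' maximising pair always lies on the hull — followed by pairwise distances
#' over the hull vertices.
#'
#' @param m a [PlantMask].
#' @return Diameter in pixels; `0` for an empty or single-pixel mask.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1, 1] <- m[5, 4] <- TRUE
#' maxDiameter(PlantMask(m))  # 3-4-5 triangle: 5
#' @export
maxDiameter <- function(m) .feret(m)$d

#' Projected shoot area
#'
#' The number of plant pixels converted to physical area; the standard 2-D
#' proxy for shoot biomass.
#'
#' @param m a [PlantMask].
#' @param mmPerPx millimetres per pixel edge (positive).
#' @return Area in square millimetres.
#' @examples
#' projectedArea(PlantMask(matrix(TRUE, 10, 10)), 0.5)  # 25 mm^2
#' @export
projectedArea <- function(m, mmPerPx) {
  if (!is.numeric(mmPerPx) || length(mmPerPx) != 1L || is.na(mmPerPx) ||
      mmPerPx <= 0)
    stop("'mmPerPx' must be a positive scalar")
  sum(m@mask) * mmPerPx^2
}

#' Measure a plant mask
#'
#' Computes the view-appropriate phenotypic parameters in millimetres:
#' x-extent, y-extent and maximum Feret diameter for top view; width and
#' height for side view; projected shoot area, pixel count and an empty-mask
#' flag for both.  Parameters belonging to the other view are `NA`.
#'
#' @param m a [PlantMask], normally the opened mask.
#' @param cfg the [ViewConfig] used for segmentation (supplies the view and
#'   the millimetre factor).
#' @param plantId,timepoint identifiers copied into the record.
#' @return A one-row `data.frame` (a `MeasurementRecord`) with columns
#'   `plant_id`, `view`, `timepoint`, `x_extent_mm`, `y_extent_mm`,
#'   `diameter_mm`, `width_mm`, `height_mm`, `projected_shoot_area_mm2`,
#'   `pixel_count`, `empty_flag`.
#' @seealso [summarizeGroups()], [runBatch()]
#' @export
measurePlant <- function(m, cfg, plantId = "plant", timepoint = "") {
  f <- cfg@mmPerPx
  if (f <= 0) stop("configuration has non-positive mmPerPx")
  npx <- sum(m@mask)
  rec <- data.frame(
    plant_id = as.character(plantId), view = cfg@view,
    timepoint = as.character(timepoint),
    x_extent_mm = NA_real_, y_extent_mm = NA_real_, diameter_mm = NA_real_,
    width_mm = NA_real_, height_mm = NA_real_,
    projected_shoot_area_mm2 = npx * f^2,
    pixel_count = as.integer(npx), empty_flag = npx == 0L,
    stringsAsFactors = FALSE
  )
  if (cfg@view == "top") {
    e <- maskExtents(m)
    rec$x_extent_mm <- e[["x_extent"]] * f
    rec$y_extent_mm <- e[["y_extent"]] * f
    rec$diameter_mm <- maxDiameter(m) * f
  } else {
    wh <- maskWidthHeight(m)
    rec$width_mm <- wh[["width"]] * f
    rec$height_mm <- wh[["height"]] * f
  }
  rec
}

#' Group means and standard errors of projected shoot area
#'
#' Summarizes measurement records per group and timepoint: arithmetic mean
#' and standard error (sample standard deviation, i.e. the n-1 form, divided
#' by `sqrt(n)`) of the projected shoot area — the quantities plotted as
#' growth curves with error bars in cultivar/treatment comparisons.
#'
#' @param records a `data.frame` of measurement records ([measurePlant()]
#'   rows or a [runBatch()] result table).
#' @param groups a `data.frame` with columns `plant_id` and `group` mapping
#'   every plant to its cultivar/condition label.
#' @return A `data.frame` with columns `group`, `timepoint`, `n`,
#'   `mean_area_mm2`, `se_area_mm2`, ordered by group then timepoint.
#'   Cells with no usable value are omitted with a warning; single-replicate
#'   cells report a standard error of 0 with a warning.
#' @examples
#' recs <- data.frame(plant_id = c("a", "b"), timepoint = "d1",
#'                    projected_shoot_area_mm2 = c(1, 3))
#' grp <- data.frame(plant_id = c("a", "b"), group = "barke_ww")
#' summarizeGroups(recs, grp)  # mean 2, SE 1
#' @export
summarizeGroups <- function(records, groups) {
  if (!all(c("plant_id", "timepoint", "projected_shoot_area_mm2") %in%
           names(records)))
    stop("'records' must contain plant_id, timepoint and projected_shoot_area_mm2")
  if (!all(c("plant_id", "group") %in% names(groups)))
    stop("'groups' must contain plant_id and group")
  miss <- setdiff(unique(records$plant_id), unique(groups$plant_id))
  if (length(miss))
    stop("no group label for plant_id(s): ", paste(miss, collapse = ", "))
  df <- merge(records, unique(groups[, c("plant_id", "group")]),
              by = "plant_id", sort = FALSE)
  cells <- unique(df[, c("group", "timepoint")])
  cells <- cells[order(cells$group, cells$timepoint), , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    v <- df$projected_shoot_area_mm2[df$group == cells$group[i] &
                                     df$timepoint == cells$timepoint[i]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      warning(sprintf("group \"%s\", timepoint \"%s\": no values; omitted",
                      cells$group[i], cells$timepoint[i]))
      next
    }
    se <- if (n == 1L) {
      warning(sprintf(
        "group \"%s\", timepoint \"%s\": single replicate; SE reported as 0",
        cells$group[i], cells$timepoint[i]))
      0
    } else stats::sd(v) / sqrt(n)
    out[[i]] <- data.frame(group = cells$group[i],
                           timepoint = cells$timepoint[i],
                           n = n, mean_area_mm2 = mean(v), se_area_mm2 = se,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(group = character(), timepoint = character(),
                      n = integer(), mean_area_mm2 = numeric(),
                      se_area_mm2 = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
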