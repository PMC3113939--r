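# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's vectorized code paths: interval tests are spelled out
# longhand per pixel, morphology scans the full neighbourhood, and the
# diameter oracle enumerates all pixel pairs.

# longhand per-pixel classifier: re-evaluates every class's intervals with
# explicit comparisons; HSV from grDevices directly
oracleClassify <- function(img, cfg) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  masks <- lapply(sceneRegions(cfg), function(r)
    rasterize(scaleRegion(r, regionScale(cfg)), w, h))
  names(masks) <- vapply(sceneRegions(cfg), function(r) r@name, character(1))
  out <- matrix(0L, h, w)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    r <- img[row, col, 1L]; g <- img[row, col, 2L]; b <- img[row, col, 3L]
    hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
    hue <- (hsv[1L] * 360) %% 360; s <- hsv[2L]; v <- hsv[3L]
    for (ci in seq_along(objectClasses(cfg))) {
      cl <- objectClasses(cfg)[[ci]]
      if (!is.na(cl@region) && !masks[[cl@region]][row, col]) next
      hit <- FALSE
      for (p in cl@profiles) {
        lo <- p@lo; hi <- p@hi
        ok <- r >= lo[["R"]] && r <= hi[["R"]] &&
              g >= lo[["G"]] && g <= hi[["G"]] &&
              b >= lo[["B"]] && b <= hi[["B"]] &&
              s >= lo[["S"]] && s <= hi[["S"]] &&
              v >= lo[["V"]] && v <= hi[["V"]]
        if (ok) {
          ok <- if (p@hWraps && lo[["H"]] > hi[["H"]])
            hue >= lo[["H"]] || hue <= hi[["H"]]
          else hue >= lo[["H"]] && hue <= hi[["H"]]
        }
        if (ok) { hit <- TRUE; break }
      }
      if (hit) { out[row, col] <- ci; break }
    }
  }
  out
}

# exhaustive neighbourhood-scan morphology (border = background)
scanErode <- function(m, rad) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    if (row - rad < 1L || row + rad > h || col - rad < 1L || col + rad > w) next
    out[row, col] <- all(m[(row - rad):(row + rad), (col - rad):(col + rad)])
  }
  out
}

scanDilate <- function(m, rad) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    rs <- max(1L, row - rad):min(h, row + rad)
    cs <- max(1L, col - rad):min(w, col + rad)
    out[row, col] <- any(m[rs, cs])
  }
  out
}

# direct min/max scan for extents (0-based pixel coordinates)
scanExtents <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) return(c(0, 0))
  c(max(idx[, 2L]) - min(idx[, 2L]) + 1, max(idx[, 1L]) - min(idx[, 1L]) + 1)
}

# full O(n^2) pairwise diameter over all true pixel centres
pairwiseDiameter <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  max(stats::dist(cbind(idx[, 2L], idx[, 1L])))
}

randomMask <- function(h, w, p = 0.3) matrix(stats::runif(h * w) < p, h, w)

randomRgbImage <- function(h, w) {
  array(sample(0:255, h * w * 3L, replace = TRUE), dim = c(h, w, 3L))
}

# randomized valid ViewConfig: 2 region-bound classes with random box
# profiles plus an unrestricted "plant" class declared last
randomViewConfig <- function(width, height, nRegionClasses = 2L) {
  randProfile <- function() {
    rgbB <- replicate(3L, sort(sample(0:255, 2L)))
    sv <- replicate(2L, sort(stats::runif(2L)))
    hWraps <- stats::runif(1L) < 0.3
    hb <- sort(stats::runif(2L, 0, 359.99))
    if (hWraps) hb <- rev(hb)
    ThresholdProfile(
      lo = c(rgbB[1L, ], hb[1L], sv[1L, ]),
      hi = c(rgbB[2L, ], hb[2L], sv[2L, ]),
      hWraps = hWraps)
  }
  randRegion <- function(nm, w, h) {
    if (stats::runif(1L) < 0.5) {
      x <- sort(stats::runif(2L, -5, w + 5)); y <- sort(stats::runif(2L, -5, h + 5))
      Region(nm, "rectangle", c(x[1L], y[1L], x[2L], y[2L]))
    } else {
      Region(nm, "circle",
             c(stats::runif(1L, 0, w), stats::runif(1L, 0, h),
               stats::runif(1L, 1, max(w, h) / 2)))
    }
  }
  regions <- lapply(seq_len(nRegionClasses), function(i)
    randRegion(paste0("reg", i), width, height))
  classes <- lapply(seq_len(nRegionClasses), function(i)
    ObjectClass(paste0("obj", i),
                lapply(seq_len(sample(1:2, 1L)), function(j) randProfile()),
                region = paste0("reg", i)))
  classes <- c(classes, list(ObjectClass("plant", list(randProfile()))))
  ViewConfig(view = sample(c("top", "side"), 1L), classes = classes,
             regions = regions,
             regionScale = stats::runif(1L, 0.5, 1.5),
             mmPerPx = stats::runif(1L, 0.2, 2),
             openingRadius = sample(0:2, 1L), configId = "random")
}
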