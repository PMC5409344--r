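# Deterministic generator of tissue-like RGB tiles with ground-truth
# nuclei masks. Emulates bright-background H&E-like tiles containing dark
# elliptical nuclei, a controllable fraction of them touching so the
# watershed de-clumping stage has work to do.

#' Configuration of a synthetic tissue scene
#'
#' Defaults describe a 64 x 64 tile with 8 violet nuclei of 3-7 px radius
#' on a near-white background, a quarter of them placed touching an
#' existing nucleus. Nucleus intensity fades quadratically from the
#' center (`edgeFade` is the fraction of contrast lost at the boundary),
#' which makes the candidate-nuclei thresholds act on the segmented
#' boundary rather than all-or-nothing. Colors are H&E-like so the
#' 210-240 background thresholds of the watershed space are meaningful.
#'
#' @param width,height tile dimensions in pixels.
#' @param nuclei number of nuclei to place.
#' @param radiusRange min/max equivalent radius in pixels (>= 2).
#' @param eccRange min/max axis ratio of the ellipses.
#' @param overlapFraction share of nuclei placed touching another.
#' @param nucleusColor,mean RGB (0-255) of nuclei.
#' @param nucleusSpread per-nucleus color jitter standard deviation.
#' @param edgeFade fraction of nucleus contrast lost at its boundary.
#' @param bgColor background mean RGB.
#' @param noiseSd per-pixel Gaussian noise standard deviation.
#' @param seed integer seed; the same config is bit-reproducible.
#' @return a list of class "SceneConfig".
#' @export
sceneConfig <- function(width = 64, height = 64, nuclei = 8,
                        radiusRange = c(3, 7), eccRange = c(1, 1.6),
                        overlapFraction = 0.25,
                        nucleusColor = c(120, 60, 160), nucleusSpread = 12,
                        edgeFade = 0.95,
                        bgColor = c(235, 225, 235), noiseSd = 8,
                        seed = 1) {
  stopifnot(width > 0, height > 0, nuclei >= 0, radiusRange[1] >= 2,
            overlapFraction >= 0, overlapFraction <= 1,
            all(nucleusColor >= 0 & nucleusColor <= 255),
            all(bgColor >= 0 & bgColor <= 255))
  structure(list(width = width, height = height, nuclei = nuclei,
                 radiusRange = radiusRange, eccRange = eccRange,
                 overlapFraction = overlapFraction,
                 nucleusColor = nucleusColor, nucleusSpread = nucleusSpread,
                 edgeFade = edgeFade, bgColor = bgColor, noiseSd = noiseSd,
                 seed = seed),
            class = "SceneConfig")
}

# Normalized squared ellipse radius of points (x, y) for an ellipse at
# (cx, cy) with semi-axes a, b rotated by theta. <= 1 inside.
ellipseRho2 <- function(x, y, cx, cy, a, b, theta) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

#' Generate one synthetic tile with its ground-truth label mask
#'
#' Ellipses are placed sequentially: the non-overlapping share with a
#' clearance margin, the overlapping share at center distance 0.75 times
#' the sum of radii from a previously placed nucleus (close enough to
#' merge into one candidate component, far enough to leave two distance
#' transform maxima). Rasterization is anti-aliased by 2x2 supersampling;
#' the ground truth labels pixels whose coverage is at least 0.5 (later
#' nuclei overwrite earlier ones on the rare shared pixels).
#'
#' @param config a [sceneConfig()].
#' @return list with `tile` (height x width x 3 array, integer values
#'   0-255) and `mask` (integer label matrix, one label per nucleus).
#' @export
generateTile <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  withLocalSeed(config$seed, {
    h <- config$height; w <- config$width
    tile <- array(rep(config$bgColor, each = h * w), dim = c(h, w, 3))
    mask <- matrix(0L, h, w)
    placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
    nOverlap <- round(config$nuclei * config$overlapFraction)
    nFree <- config$nuclei - nOverlap
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)

    for (i in seq_len(config$nuclei)) {
      r <- runif(1, config$radiusRange[1], config$radiusRange[2])
      ecc <- runif(1, config$eccRange[1], config$eccRange[2])
      a <- r * sqrt(ecc); b <- r / sqrt(ecc)
      theta <- runif(1, 0, pi)
      touching <- i > nFree && nrow(placed) > 0
      ok <- FALSE
      for (attempt in seq_len(500)) {
        if (touching) {
          j <- sample.int(nrow(placed), 1)
          ang <- runif(1, 0, 2 * pi)
          d <- 0.75 * (r + placed$r[j])
          cx <- placed$cx[j] + d * cos(ang)
          cy <- placed$cy[j] + d * sin(ang)
          if (cx < a + 1 || cx > w - a || cy < a + 1 || cy > h - a) next
          # must not crowd a third nucleus
          others <- setdiff(seq_len(nrow(placed)), j)
          if (length(others) &&
              any(sqrt((placed$cx[others] - cx)^2 + (placed$cy[others] - cy)^2) <
                  1.3 * (placed$r[others] + r))) next
        } else {
          cx <- runif(1, a + 1, w - a)
          cy <- runif(1, a + 1, h - a)
          if (nrow(placed) &&
              any(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) <
                  1.3 * (placed$r + r))) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place the requested nuclei count; lower the density",
             call. = FALSE)
      placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r))

      color <- pmin(pmax(config$nucleusColor +
                           rnorm(3, 0, config$nucleusSpread), 0), 255)
      # bounding box
      ext <- a + 1.5
      c0 <- max(1, floor(cx - ext)); c1 <- min(w, ceiling(cx + ext))
      r0 <- max(1, floor(cy - ext)); r1 <- min(h, ceiling(cy + ext))
      sub <- expand.grid(y = r0:r1, x = c0:c1)
      # 2x2 supersampled coverage
      cov <- 0
      for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25))
        cov <- cov + (ellipseRho2(sub$x + ox, sub$y + oy, cx, cy, a, b, theta) <= 1)
      cov <- cov / 4
      rho2 <- pmin(ellipseRho2(sub$x, sub$y, cx, cy, a, b, theta), 1)
      wgt <- cov * (1 - config$edgeFade * rho2)
      idx <- cbind(sub$y, sub$x)
      for (ch in 1:3) {
        plane <- tile[, , ch]
        plane[idx] <- (1 - wgt) * plane[idx] + wgt * color[ch]
        tile[, , ch] <- plane
      }
      mask[idx[cov >= 0.5, , drop = FALSE]] <- i
    }

    if (config$noiseSd > 0)
      tile <- tile + array(rnorm(h * w * 3, 0, config$noiseSd), dim = c(h, w, 3))
    tile <- round(pmin(pmax(tile, 0), 255))
    list(tile = tile, mask = mask)
  })
}

#' Generate a cohort of tiles with a manifest
#'
#' Per-tile seeds are derived from the master seed, so a cohort is fully
#' reproducible from `(configTemplate, masterSeed)`. With `dir` set, tiles
#' and label masks are written as PNG and a `manifest.csv` records file
#' names, seeds and nuclei counts.
#'
#' @param nTiles number of tiles (>= 1).
#' @param config a [sceneConfig()] template (its seed is ignored).
#' @param masterSeed integer master seed.
#' @param dir optional output directory.
#' @return list with `tiles`, `masks` (lists) and `manifest` (data.frame).
#' @export
generateCohort <- function(nTiles, config = sceneConfig(), masterSeed = 1,
                           dir = NULL) {
  stopifnot(nTiles >= 1)
  tiles <- masks <- vector("list", nTiles)
  rows <- vector("list", nTiles)
  for (i in seq_len(nTiles)) {
    cfg <- config
    cfg$seed <- deriveSeed(masterSeed, i)
    out <- generateTile(cfg)
    tiles[[i]] <- out$tile
    masks[[i]] <- out$mask
    tileFile <- maskFile <- NA_character_
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      tileFile <- sprintf("tile_%03d.png", i)
      maskFile <- sprintf("mask_%03d.png", i)
      writeTile(out$tile, file.path(dir, tileFile))
      writeMask(out$mask, file.path(dir, maskFile), labeled = TRUE)
    }
    rows[[i]] <- data.frame(index = i, tile = tileFile, mask = maskFile,
                            seed = cfg$seed, nuclei = max(out$mask))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(tiles = tiles, masks = masks, manifest = manifest)
}

#' Seeded train/test split of a cohort
#'
#' @param nTiles cohort size.
#' @param nTrain number of training tiles.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint).
#' @export
trainTestSplit <- function(nTiles, nTrain, seed = 1) {
  stopifnot(nTrain >= 1, nTrain < nTiles)
  train <- withLocalSeed(seed, sort(sample.int(nTiles, nTrain)))
  list(train = train, test = setdiff(seq_len(nTiles), train))
}

#' Read or write an RGB tile
#'
#' @param path PNG or TIFF file path.
#' @return `readTile`: height x width x 3 array with values 0-255.
#' @export
readTile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported tile format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  round(img[, , 1:3] * 255)
}

#' @rdname readTile
#' @param tile height x width x 3 array, values 0-255.
#' @export
writeTile <- function(tile, path) {
  img <- pmin(pmax(tile / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported tile format: ", ext))
  invisible(path)
}
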