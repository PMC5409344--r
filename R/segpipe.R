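# Bundled reference workflow: a simplified watershed-style nuclei
# segmentation pipeline. Stages mirror the classic chain background
# detection -> candidate nuclei (morphological reconstruction) -> area
# filter -> hole filling -> watershed de-clumping -> final area filter.
# Every stage is pure and deterministic, the contract the SA machinery
# (dummy-parameter effects exactly zero) and the compact-composition
# executor rely on.

connOf <- function(v) {
  if (v %in% c("4-conn", "4", 4)) 4L
  else if (v %in% c("8-conn", "8", 8)) 8L
  else stop("connectivity must be '4-conn' or '8-conn'", call. = FALSE)
}

# Window radius of the grayscale erosion that seeds opening-by-
# reconstruction; covers nuclei up to ~8 px radius so they are leveled
# by the background estimate and stand out in the top-hat residue.
.RECON_RADIUS <- 8L

#' Tissue / background detection
#'
#' A pixel is tissue iff any channel falls below its threshold
#' (`r < R or g < G or b < B`); bright near-white pixels are background.
#'
#' @param tile RGB array (height x width x 3, values 0-255).
#' @param B,G,R channel thresholds (0-255).
#' @return binary tissue mask (integer matrix).
#' @export
backgroundDetect <- function(tile, B, G, R) {
  ((tile[, , 1] < R) | (tile[, , 2] < G) | (tile[, , 3] < B)) * 1L
}

#' Candidate nuclei extraction
#'
#' The tile is converted to an inverted grayscale (nuclei bright),
#' restricted to the tissue mask, and background shading is estimated by
#' opening-by-reconstruction (grayscale erosion followed by morphological
#' reconstruction under the image, with the `MorphRecon` propagation
#' neighborhood). Subtracting the reconstruction leaves a top-hat residue
#' in which nuclei are peaks. Candidates are the components of the
#' permissive threshold `residue >= min(G1, G2)` that contain at least
#' one seed pixel at the strict threshold `residue >= max(G1, G2)`
#' (hysteresis); raising either threshold never adds components.
#'
#' @param tile RGB array (0-255).
#' @param tissueMask binary mask from [backgroundDetect()].
#' @param G1,G2 candidate-nuclei thresholds (gray levels).
#' @param MorphRecon propagation neighborhood, "4-conn" or "8-conn".
#' @return binary candidate mask.
#' @export
candidateNuclei <- function(tile, tissueMask, G1, G2, MorphRecon = "8-conn") {
  conn <- connOf(MorphRecon)
  gray <- 255 - (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  gray <- gray * (tissueMask > 0)
  marker <- erode_min_cpp(gray, .RECON_RADIUS)
  recon <- reconstruct_cpp(pmin(marker, gray), gray, conn)
  residue <- gray - recon
  extent <- (residue >= min(G1, G2)) * 1L
  seeds <- residue >= max(G1, G2)
  lab <- cc_label_cpp(extent, conn)
  if (max(lab) == 0L) return(extent * 0L)
  keep <- sort(unique(lab[seeds & lab > 0]))
  matrix(as.integer(lab %in% keep), nrow = nrow(lab))
}

#' Connected-component area filter
#'
#' Removes components (under the given connectivity) whose pixel area is
#' below `minArea` or above `maxArea`.
#'
#' @param mask binary mask.
#' @param minArea,maxArea inclusive area bounds.
#' @param connectivity "4-conn" or "8-conn" (default).
#' @return filtered binary mask.
#' @export
sizeFilter <- function(mask, minArea = 0, maxArea = Inf, connectivity = "8-conn") {
  if (minArea > maxArea) stop("minArea must be <= maxArea")
  mask <- asBinaryMask(mask)
  lab <- cc_label_cpp(mask, connOf(connectivity))
  if (max(lab) == 0L) return(mask)
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(area >= minArea & area <= maxArea)
  matrix(as.integer(lab %in% keep), nrow = nrow(lab))
}

# Same filter on an integer label image, preserving labels.
sizeFilterLabels <- function(labels, minArea = 0, maxArea = Inf) {
  if (max(labels) == 0L) return(labels)
  area <- tabulate(labels[labels > 0], nbins = max(labels))
  drop <- which(area < minArea | area > maxArea)
  labels[labels %in% drop] <- 0L
  labels
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected to the image border become
#' foreground. The foreground propagation neighborhood determines the
#' background connectivity by the usual complementary convention
#' (4-conn foreground pairs with 8-conn background and vice versa).
#'
#' @param mask binary mask.
#' @param FillHoles propagation neighborhood, "4-conn" or "8-conn".
#' @return binary mask with holes filled.
#' @export
fillHoles <- function(mask, FillHoles = "8-conn") {
  mask <- asBinaryMask(mask)
  bgConn <- if (connOf(FillHoles) == 4L) 8L else 4L
  bg <- 1L - mask
  lab <- cc_label_cpp(bg, bgConn)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- bg == 1L & !(lab %in% border)
  mask[hole] <- 1L
  mask
}

#' Split touching nuclei by marker-based watershed
#'
#' Components smaller than `MinSizePl` are dropped; the remaining
#' foreground is partitioned by flooding the negated Euclidean distance
#' transform from markers at the transform's extended maxima (regional
#' maxima of the h-maxima transform). The merge depth `h` is tied to
#' `MinSizePl` — peaks separated by a valley shallower than half the
#' radius of a `MinSizePl`-area disk are treated as one nucleus, so ridge
#' wobble along an elongated nucleus does not fragment it. Any retained
#' component that ends up without a marker gets one at its distance
#' maximum, so the labels partition the retained foreground exactly.
#'
#' @param mask binary mask.
#' @param Watershed propagation neighborhood, "4-conn" or "8-conn".
#' @param MinSizePl minimum component area kept before splitting.
#' @return integer label matrix (0 is background).
#' @export
watershedSplit <- function(mask, Watershed = "8-conn", MinSizePl = 0) {
  conn <- connOf(Watershed)
  mask <- sizeFilter(mask, minArea = MinSizePl, connectivity = Watershed)
  if (sum(mask) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  dist <- edt_cpp(mask)
  h <- max(1, 0.5 * sqrt(MinSizePl / pi))
  hmax <- reconstruct_cpp(pmax(dist - h, 0), dist, conn)
  delta <- 0.01  # regional maxima of the h-maxima transform
  rmax <- (hmax - reconstruct_cpp(pmax(hmax - delta, 0), hmax, conn)) > delta / 2
  markers <- cc_label_cpp((rmax & mask > 0) * 1L, conn)
  comp <- cc_label_cpp(mask, conn)
  missing <- setdiff(seq_len(max(comp)), unique(comp[markers > 0]))
  if (length(missing)) {
    nxt <- max(markers)
    for (cm in missing) {
      idx <- which(comp == cm)
      markers[idx[which.max(dist[idx])]] <- nxt <- nxt + 1L
    }
  }
  watershed_cpp(-dist, markers, mask, conn)
}

#' The bundled watershed parameter space
#'
#' Reads the packaged YAML description of the watershed workflow's
#' 15-parameter space (background thresholds B/G/R; red-blood-cell
#' thresholds T1/T2, declared but inert in this simplified pipeline;
#' candidate-nuclei thresholds G1/G2; the area bounds; and the three
#' propagation neighborhoods), discretized at `p = 20` levels.
#'
#' @param includeDummy append a `Dummy` control parameter consumed by no
#'   stage (its MOAT effects measure the stochastic output component,
#'   exactly zero for this deterministic pipeline).
#' @return a [ParameterSpace-class].
#' @export
watershedSpace <- function(includeDummy = FALSE) {
  path <- system.file("extdata", "watershed_space.yaml", package = "segstudy")
  space <- readParameterSpace(path)
  if (includeDummy) {
    space@specs <- c(space@specs,
                     list(parameterSpec("Dummy", "continuous", low = 0, high = 1,
                                        default = 0.5, dummy = TRUE)))
    validObject(space)
  }
  space
}

#' The reference pipeline as an executable stage chain
#'
#' Six pure stages: background detection (B, G, R), candidate nuclei
#' (G1, G2, MorphRecon), candidate area filter (MinSize, MaxSize), hole
#' filling (FillHoles), watershed splitting (Watershed, MinSizePl) and
#' the final area filter (MinSizeSeg, MaxSizeSeg). Stage inputs/outputs
#' are lists carrying the tile and the evolving mask, so the dataflow
#' executor can merge instances that agree on a prefix of bound
#' parameter values.
#'
#' @return a [SegPipeline-class].
#' @export
watershedPipeline <- function() {
  new("SegPipeline", stages = list(
    list(name = "background", params = c("B", "G", "R"),
         fn = function(input, p)
           list(tile = input$tile,
                mask = backgroundDetect(input$tile, p$B, p$G, p$R))),
    list(name = "candidates", params = c("G1", "G2", "MorphRecon"),
         fn = function(input, p)
           list(mask = candidateNuclei(input$tile, input$mask,
                                       p$G1, p$G2, p$MorphRecon))),
    list(name = "sizefilter", params = c("MinSize", "MaxSize"),
         fn = function(input, p)
           list(mask = sizeFilter(input$mask, p$MinSize, p$MaxSize))),
    list(name = "fillholes", params = "FillHoles",
         fn = function(input, p)
           list(mask = fillHoles(input$mask, p$FillHoles))),
    list(name = "watershed", params = c("Watershed", "MinSizePl"),
         fn = function(input, p) {
           lab <- watershedSplit(input$mask, p$Watershed, p$MinSizePl)
           list(labels = lab)
         }),
    list(name = "sizefilterseg", params = c("MinSizeSeg", "MaxSizeSeg"),
         fn = function(input, p) {
           lab <- sizeFilterLabels(input$labels, p$MinSizeSeg, p$MaxSizeSeg)
           list(labels = lab, mask = (lab > 0) * 1L)
         })
  ))
}

setMethod("show", "SegPipeline", function(object) {
  cat(sprintf("SegPipeline with %d stages:\n", length(object@stages)))
  for (s in object@stages)
    cat(sprintf("  %-14s params: %s\n", s$name, paste(s$params, collapse = ", ")))
})

#' Run the reference pipeline on one tile
#'
#' Executes the six-stage chain directly (without the dataflow executor)
#' and returns the final binary mask together with every intermediate
#' stage output. Parameters the pipeline does not consume (T1, T2, any
#' dummy) are accepted and ignored.
#'
#' @param tile RGB array (height x width x 3, values 0-255).
#' @param params named list of native-unit parameter values; missing
#'   entries fall back to the bundled space's defaults.
#' @return list with `mask` (final binary mask), `labels` (final nucleus
#'   labels) and `stages` (named list of per-stage outputs).
#' @export
runPipeline <- function(tile, params = list()) {
  defaults <- defaultPoint(watershedSpace())
  params <- utils::modifyList(defaults, as.list(params))
  pipe <- watershedPipeline()
  state <- list(tile = tile)
  stages <- list()
  for (s in pipe@stages) {
    state <- s$fn(state, params[s$params])
    stages[[s$name]] <- state
  }
  list(mask = state$mask, labels = state$labels, stages = stages)
}
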