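# Mask-comparison metrics: SA phases score runs with the XOR pixel count
# against a reference mask; tuning maximizes Dice or Jaccard.

asBinaryMask <- function(m) {
  if (is.logical(m)) m <- m * 1L
  m <- as.matrix(m)
  (m > 0) * 1L
}

checkDims <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("mask dimension mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
}

#' Mask-comparison metrics
#'
#' `xorCount` is the number of disagreeing pixels (the screening metric);
#' `diceCoef` is `2|A n B| / (|A| + |B|)` and `jaccardCoef` is
#' `|A n B| / |A u B|` (the tuning objectives). Labeled masks are
#' binarized (label > 0 is foreground). Two empty masks score 1.0 on Dice
#' and Jaccard — an all-background tile segmented as all-background is
#' perfect agreement. The identities `J = D / (2 - D)`,
#' `dice >= jaccard` and `xor = |A| + |B| - 2|A n B|` always hold.
#'
#' @param a,b masks of equal dimensions (0/1, logical, or labeled).
#' @return `xorCount`: a non-negative integer count; `diceCoef` and
#'   `jaccardCoef`: a value in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' diceCoef(a, b)     # 0.5
#' jaccardCoef(a, b)  # 1/3
#' xorCount(a, b)     # 2
#' @export
xorCount <- function(a, b) {
  a <- asBinaryMask(a); b <- asBinaryMask(b)
  checkDims(a, b)
  sum(a != b)
}

#' @rdname xorCount
#' @export
diceCoef <- function(a, b) {
  a <- asBinaryMask(a); b <- asBinaryMask(b)
  checkDims(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' @rdname xorCount
#' @export
jaccardCoef <- function(a, b) {
  a <- asBinaryMask(a); b <- asBinaryMask(b)
  checkDims(a, b)
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Read or write a mask image
#'
#' Masks are single-channel PNG or TIFF; any nonzero pixel is foreground.
#' With `labeled = TRUE` integer labels are preserved: PNG encodes
#' `label / 255` (8-bit, up to 255 labels), TIFF encodes `label / 65535`
#' (16-bit).
#'
#' @param path file path; format chosen by extension (.png/.tif/.tiff).
#' @param labeled read/write integer labels instead of a binary mask.
#' @return `readMask`: an integer matrix; `writeMask`: `path`, invisibly.
#' @export
readMask <- function(path, labeled = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!labeled) return((img > 0) * 1L)
  denom <- if (ext == "png") 255 else 65535
  matrix(as.integer(round(img * denom)), nrow = nrow(img))
}

#' @rdname readMask
#' @param mask matrix to write (0/1 or integer labels).
#' @export
writeMask <- function(mask, path, labeled = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (labeled) {
    denom <- if (ext == "png") 255 else 65535
    if (max(mask) > denom)
      stop(sprintf("too many labels for a %s mask (max %d)", ext, denom),
           call. = FALSE)
    img <- mask / denom
  } else img <- (mask > 0) * 1
  img <- matrix(pmin(pmax(img, 0), 1), nrow = nrow(mask))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported mask format: ", ext))
  invisible(path)
}
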