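# Canny edge detection on spectrogram images: Gaussian blur and Sobel
# gradients via EBImage, then non-maximum suppression and hysteresis
# thresholding (connected weak-edge components are kept only when they
# touch a strong edge, found with EBImage's connected-component labeling).

#' Canny edge map of an image matrix
#'
#' @param img numeric matrix (values on any scale; thresholds are relative
#'   to the maximum gradient magnitude).
#' @param sigma Gaussian blur standard deviation in pixels (default 2).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.1 / 0.3).
#' @return logical matrix of edge pixels, same dimensions as `img`.
#' @export
canny_edges <- function(img, sigma = 2, low = 0.1, high = 0.3) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (low > high) stop("need low <= high")
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(sm, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(sm, ky, boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  # suppress the 2-pixel image border where padding gradients are artifacts
  mag[c(1, 2, nrow(mag) - 1, nrow(mag)), ] <- 0
  mag[, c(1, 2, ncol(mag) - 1, ncol(mag))] <- 0
  mmax <- max(mag)
  if (mmax <= 1e-12) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx)
  nms <- nonmax_suppress(mag, ang)
  strong <- nms >= high * mmax
  weak <- nms >= low * mmax
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(img), ncol(img))
}

# thin gradient ridges: keep a pixel only if its magnitude is at least
# that of both neighbors along the quantized gradient direction
nonmax_suppress <- function(mag, ang) {
  nr <- nrow(mag); nc <- ncol(mag)
  # direction quantized to 0, 45, 90, 135 degrees
  a <- (ang %% pi)
  dir <- findInterval(a, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  offs <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
  out <- matrix(0, nr, nc)
  for (d in 0:3) {
    o <- offs[[as.character(d)]]
    n1 <- shift(mag, o[1], o[2])
    n2 <- shift(mag, -o[1], -o[2])
    sel <- dir == d & mag >= n1 & mag >= n2
    out[sel] <- mag[sel]
  }
  out
}
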