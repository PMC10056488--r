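# 2D ridge filters shared by the OCT border pipeline.

# Scale-normalized 2D Hessian of an image at Gaussian scale sigma (px).
hessian2d <- function(img, sigma) {
  s <- .cpp_gauss2d(img, sigma)
  nr <- nrow(s); nc <- ncol(s)
  ext <- function(m, di, dj) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    m[ri, ci, drop = FALSE]
  }
  dxx <- ext(s, 1, 0) - 2 * s + ext(s, -1, 0)
  dyy <- ext(s, 0, 1) - 2 * s + ext(s, 0, -1)
  dxy <- (ext(s, 1, 1) - ext(s, 1, -1) - ext(s, -1, 1) + ext(s, -1, -1)) / 4
  k <- sigma^2
  list(dxx = k * dxx, dxy = k * dxy, dyy = k * dyy)
}

#' Single-scale 2D Frangi vesselness
#'
#' Hessian-eigenvalue ridge filter for elongated structures at one Gaussian
#' scale. For a ring (annulus) of thickness `t` px, the matched scale is
#' `t / (2 * sqrt(3))`.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian scale in px.
#' @param polarity `"dark"` to enhance dark ridges on bright background,
#'   `"bright"` for the opposite.
#' @param beta blob-ness sensitivity.
#' @param c_frac structureness scale as a fraction of the maximum Frobenius
#'   Hessian norm.
#' @return matrix of vesselness responses in [0, 1].
#' @export
frangi2d <- function(img, sigma, polarity = c("dark", "bright"), beta = 0.5,
                     c_frac = 0.5) {
  polarity <- match.arg(polarity)
  h <- hessian2d(img, sigma)
  tr <- h$dxx + h$dyy
  det <- h$dxx * h$dyy - h$dxy^2
  tmp <- sqrt(pmax(tr^2 / 4 - det, 0))
  e1 <- tr / 2 - tmp  # smaller
  e2 <- tr / 2 + tmp  # larger
  # lambda2 = eigenvalue of larger magnitude
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  S <- sqrt(l1^2 + l2^2)
  cc <- c_frac * max(S)
  if (cc <= 0) return(matrix(0, nrow(img), ncol(img)))
  Rb <- ifelse(abs(l2) > 0, abs(l1) / abs(l2), 0)
  v <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
  keep <- if (polarity == "dark") l2 > 0 else l2 < 0
  v[!keep] <- 0
  v
}

# Harris--Stephens corner response (k = 0.04), Gaussian window.
harris_response <- function(img, sigma_d = 1, sigma_i = 2, k = 0.04) {
  s <- .cpp_gauss2d(img, sigma_d)
  nr <- nrow(s); nc <- ncol(s)
  ext <- function(m, di, dj) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    ci <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    m[ri, ci, drop = FALSE]
  }
  ix <- (ext(s, 1, 0) - ext(s, -1, 0)) / 2
  iy <- (ext(s, 0, 1) - ext(s, 0, -1)) / 2
  sxx <- .cpp_gauss2d(ix * ix, sigma_i)
  syy <- .cpp_gauss2d(iy * iy, sigma_i)
  sxy <- .cpp_gauss2d(ix * iy, sigma_i)
  (sxx * syy - sxy^2) - k * (sxx + syy)^2
}
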