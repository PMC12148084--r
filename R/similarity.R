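#' @include field.R
NULL

#' Similarity configuration
#'
#' @param patchSize odd patch side length in pixels (default 13)
#' @param scales integer decimation factors (default full and half
#'   resolution)
#' @param useSobel include signed Sobel-x and Sobel-y channels
#' @return a [SimilarityConfig-class]
#' @export
similarityConfig <- function(patchSize = 13L, scales = c(1L, 2L),
                             useSobel = TRUE) {
  new("SimilarityConfig", patchSize = as.integer(patchSize),
      scales = as.integer(scales), useSobel = useSobel)
}

# ---- small image helpers --------------------------------------------------

# Sum over (2r+1)^2 windows, returned on the valid-centre grid.
.boxSum <- function(m, r) {
  w <- 2L * r + 1L
  cs <- rbind(0, apply(m, 2, cumsum))
  v <- cs[(w + 1L):nrow(cs), , drop = FALSE] -
       cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- cbind(0, t(apply(v, 1, cumsum)))
  cs2[, (w + 1L):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

# Adjoint of .boxSum: spread valid-centre values back over their windows.
.boxSpread <- function(centers, r, fullDim) {
  pad <- matrix(0, fullDim[1] + 2L * r, fullDim[2] + 2L * r)
  pad[2L * r + seq_len(nrow(centers)), 2L * r + seq_len(ncol(centers))] <-
    centers
  .boxSum(pad, r)
}

.sobelX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
.sobelY <- t(.sobelX)

# 3x3 "same" convolution with zero padding, via shift-and-add.
.conv3 <- function(img, k) {
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    kv <- k[di + 2, dj + 2]
    if (kv == 0) next
    si <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 - dj):min(n2, n2 - dj)
    out[si, sj] <- out[si, sj] + kv * img[si + di, sj + dj]
  }
  out
}

# Adjoint of .conv3: convolution with the flipped kernel.
.conv3T <- function(img, k) .conv3(img, k[3:1, 3:1])

.downsample <- function(img, f) {
  if (f == 1L) return(img)
  n1 <- (nrow(img) %/% f) * f
  n2 <- (ncol(img) %/% f) * f
  img <- img[seq_len(n1), seq_len(n2), drop = FALSE]
  a <- array(img, c(f, n1 %/% f, f, n2 %/% f))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

.upspread <- function(g, f, fullDim) {
  if (f == 1L) return(g)
  out <- matrix(0, fullDim[1], fullDim[2])
  big <- g[rep(seq_len(nrow(g)), each = f), rep(seq_len(ncol(g)), each = f),
           drop = FALSE] / f^2
  out[seq_len(nrow(big)), seq_len(ncol(big))] <- big
  out
}

# Patchwise zero-normalized cross-correlation of one channel pair, with
# optional gradient with respect to `b`. Patches with (near-)zero variance
# in either image are excluded from the patch mean.
.pncc <- function(a, b, r, grad = FALSE, varTol = 1e-12) {
  n <- (2 * r + 1)^2
  if (nrow(a) < 2 * r + 1 || ncol(a) < 2 * r + 1)
    stop("image smaller than the NCC patch", call. = FALSE)
  sa <- .boxSum(a, r);  sb <- .boxSum(b, r)
  saa <- .boxSum(a * a, r) - sa^2 / n
  sbb <- .boxSum(b * b, r) - sb^2 / n
  sab <- .boxSum(a * b, r) - sa * sb / n
  valid <- saa > varTol & sbb > varTol
  if (!any(valid)) {
    val <- 0
    if (!grad) return(list(value = val))
    return(list(value = val, grad = matrix(0, nrow(b), ncol(b))))
  }
  denom <- sqrt(pmax(saa * sbb, .Machine$double.xmin))
  ncc <- ifelse(valid, sab / denom, 0)
  nv <- sum(valid)
  val <- sum(ncc) / nv
  if (!grad) return(list(value = val))
  alpha <- ifelse(valid, 1 / denom, 0)
  gamma <- ifelse(valid, ncc / sbb, 0)
  abar <- sa / n
  bbar <- sb / n
  fullDim <- dim(b)
  g <- (a * .boxSpread(alpha, r, fullDim) -
        .boxSpread(alpha * abar, r, fullDim) -
        b * .boxSpread(gamma, r, fullDim) +
        .boxSpread(gamma * bbar, r, fullDim)) / nv
  list(value = val, grad = g)
}

#' Multiscale patchwise normalized cross-correlation
#'
#' Mean over scales and channels (raw intensity plus, optionally, signed
#' Sobel-x and Sobel-y derivatives) of the mean patchwise zero-normalized
#' cross-correlation. Equals 1 when the images are related by a positive
#' affine intensity map, and -1 for anti-correlated images. Differentiable
#' in the second image; flat (zero-variance) patches are excluded from the
#' patch mean.
#'
#' @param a fixed image (matrix)
#' @param b moving/rendered image (matrix, same shape)
#' @param cfg a [SimilarityConfig-class]
#' @param gradient also return the gradient with respect to `b`
#' @return scalar in `[-1, 1]`, or `list(value, grad)` when
#'   `gradient = TRUE`
#' @export
multiscaleNCC <- function(a, b, cfg = similarityConfig(), gradient = FALSE) {
  if (!all(dim(a) == dim(b)))
    stop("images must have the same shape", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("images must be finite", call. = FALSE)
  r <- (cfg@patchSize - 1L) %/% 2L
  nScale <- length(cfg@scales)
  nChan <- if (cfg@useSobel) 3L else 1L
  total <- 0
  gtotal <- if (gradient) matrix(0, nrow(b), ncol(b)) else NULL
  for (f in cfg@scales) {
    as <- .downsample(a, f)
    bs <- .downsample(b, f)
    gscale <- if (gradient) matrix(0, nrow(bs), ncol(bs)) else NULL
    res <- .pncc(as, bs, r, grad = gradient)
    total <- total + res$value
    if (gradient) gscale <- gscale + res$grad
    if (cfg@useSobel) {
      for (k in list(.sobelX, .sobelY)) {
        ga <- .conv3(as, k)
        gb <- .conv3(bs, k)
        # drop the outer ring: zero padding manufactures edges there that
        # would break the affine-intensity invariance of the channel
        n1 <- nrow(ga); n2 <- ncol(ga)
        ia <- if (n1 > 2) 2:(n1 - 1) else seq_len(n1)
        ja <- if (n2 > 2) 2:(n2 - 1) else seq_len(n2)
        res <- .pncc(ga[ia, ja, drop = FALSE], gb[ia, ja, drop = FALSE], r,
                     grad = gradient)
        total <- total + res$value
        if (gradient) {
          gfull <- matrix(0, n1, n2)
          gfull[ia, ja] <- res$grad
          gscale <- gscale + .conv3T(gfull, k)
        }
      }
    }
    if (gradient) gtotal <- gtotal + .upspread(gscale, f, dim(b))
  }
  val <- total / (nScale * nChan)
  if (!gradient) return(val)
  list(value = val, grad = gtotal / (nScale * nChan))
}
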