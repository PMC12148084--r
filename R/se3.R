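#' @include AllGenerics.R
NULL

# ---- SE(3) Lie group: closed-form exponential and logarithm maps ----------
#
# Twists are length-6 vectors (wx, wy, wz, vx, vy, vz): the axis-angle
# rotational tangent component (radians) first, then the translational
# component (mm). The closed forms are the standard Rodrigues rotation
# formula together with the left Jacobian V(theta), with a Taylor branch
# below theta < 1e-6 to avoid division by zero. The logarithm requires the
# rotation angle to be strictly below pi; registration twists are small, so
# this is a safe domain restriction.

.hat3 <- function(w) {
  matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
}

.checkTwist <- function(xi) {
  if (length(xi) != 6L || !all(is.finite(xi)))
    stop("a twist must be 6 finite values (rot, trans)", call. = FALSE)
  invisible(xi)
}

.checkRigid <- function(T, tol = 1e-8) {
  if (!is.matrix(T) || !all(dim(T) == c(4, 4)) || any(!is.finite(T)))
    stop("a rigid transform must be a finite 4x4 matrix", call. = FALSE)
  R <- T[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("matrix is not a rigid transform (rotation block fails R'R = I, det = +1)",
         call. = FALSE)
  if (max(abs(T[4, ] - c(0, 0, 0, 1))) > tol)
    stop("last row of a rigid transform must be (0, 0, 0, 1)", call. = FALSE)
  invisible(T)
}

#' Exponential map from se(3) twists to SE(3) rigid transforms
#'
#' @param xi length-6 twist `(rot, trans)`: axis-angle rotation (radians)
#'   first, translation (mm) last.
#' @return a 4x4 homogeneous rigid transform
#' @examples
#' expSE3(c(0, 0, pi / 2, 0, 0, 0))  # 90 degree rotation about z
#' @seealso [logSE3()], [expSE3Batch()]
#' @export
expSE3 <- function(xi) {
  .checkTwist(xi)
  row <- cpp_exp_se3_batch(matrix(xi, 1, 6))
  T <- diag(4)
  T[1:3, 1:3] <- matrix(row[1, 1:9], 3, 3, byrow = TRUE)
  T[1:3, 4] <- row[1, 10:12]
  T
}

#' Logarithm map from SE(3) to se(3)
#'
#' Inverse of [expSE3()] for rotation angles strictly below pi;
#' `expSE3(logSE3(T))` reproduces `T` to 1e-9.
#'
#' @param T 4x4 rigid transform
#' @param tol rejection margin for rotation angles near pi
#' @return length-6 twist `(rot, trans)`
#' @export
logSE3 <- function(T, tol = 1e-6) {
  .checkRigid(T)
  R <- T[1:3, 1:3]
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(ct)
  if (theta >= pi - tol)
    stop("rotation angle too close to pi; logarithm is not unique",
         call. = FALSE)
  vee <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w <- if (theta < 1e-6) {
    0.5 * (1 + theta^2 / 6) * vee
  } else {
    theta / (2 * sin(theta)) * vee
  }
  W <- .hat3(w)
  th2 <- sum(w^2)
  c2 <- if (theta < 1e-6) {
    1 / 12 + th2 / 720
  } else {
    A <- sin(theta) / theta
    B <- (1 - cos(theta)) / theta^2
    (1 - A / (2 * B)) / th2
  }
  Vinv <- diag(3) - 0.5 * W + c2 * (W %*% W)
  c(w, as.vector(Vinv %*% T[1:3, 4]))
}

#' Batched exponential map
#'
#' Vectorized over the rows of a twist table; row `i` of the result equals
#' `expSE3` of row `i`, bit-compatible with the per-row loop.
#'
#' @param xi n x 6 matrix of twists
#' @return a 4 x 4 x n array of rigid transforms
#' @export
expSE3Batch <- function(xi) {
  if (!is.matrix(xi) || ncol(xi) != 6L)
    stop("xi must be an n x 6 twist matrix", call. = FALSE)
  rows <- cpp_exp_se3_batch(xi)
  n <- nrow(xi)
  out <- array(0, c(4, 4, n))
  out[4, 4, ] <- 1
  for (i in seq_len(n)) {
    out[1:3, 1:3, i] <- matrix(rows[i, 1:9], 3, 3, byrow = TRUE)
    out[1:3, 4, i] <- rows[i, 10:12]
  }
  out
}

#' Serialize/deserialize twists and transforms as plain JSON vectors
#'
#' Twists are length-6 JSON arrays; transforms are row-major 16-element
#' arrays.
#' @param twists K x 6 twist matrix
#' @param ids optional structure ids
#' @param path file path
#' @return `readTwists` returns a list with `twists` and `ids`
#' @export
writeTwists <- function(twists, path, ids = seq_len(nrow(twists))) {
  obj <- list(ids = as.integer(ids),
              twists = lapply(seq_len(nrow(twists)),
                              function(i) unname(twists[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeTwists
#' @export
readTwists <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tw <- obj$twists
  if (is.list(tw)) tw <- do.call(rbind, tw)
  list(twists = matrix(as.numeric(tw), ncol = 6), ids = as.integer(obj$ids))
}
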