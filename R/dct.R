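## Orthonormal DCT-II machinery shared by block matching (2-D prefilter
## transform) and collaborative filtering (separable 4-D transform).

.dct_cache <- new.env(parent = emptyenv())

#' Orthonormal DCT-II matrix
#'
#' Returns the `n x n` orthonormal type-II discrete cosine transform matrix
#' `C`, with `C %*% t(C) = I`; `C %*% x` transforms a length-`n` signal.
#' Matrices are cached per size. A DCT of any length is orthonormal, so group
#' axes whose size is not a power of two need no padding.
#'
#' @param n transform length (>= 1).
#' @return `n x n` numeric matrix.
#' @export
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  if (n < 1) stop_input("DCT length must be >= 1")
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  .dct_cache[[key]] <- C
  C
}

## multiply matrix M along one axis of an nd-array
axis_apply <- function(x, M, axis) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(axis, seq_len(nd)[-axis])
  xp <- aperm(x, perm)
  y <- M %*% matrix(xp, d[axis], prod(d[-axis]))
  dim(y) <- c(d[axis], d[-axis])
  aperm(y, order(perm))
}

#' Separable orthonormal 4-D DCT of a block group
#'
#' Applies the orthonormal DCT-II along each of the four axes of a matched
#' block stack `N x N x |T| x |S|` (two spatial axes, the temporal frame axis,
#' and the group axis). Because each factor is orthonormal, the transform is
#' energy preserving and [inverse_transform_4d()] is its exact adjoint.
#'
#' @param stack 4-D numeric array.
#' @return coefficient array of the same shape.
#' @export
transform_4d <- function(stack) {
  d <- dim(stack)
  if (length(d) != 4L) stop_input("transform_4d expects a 4-D array")
  for (ax in 1:4) stack <- axis_apply(stack, dct_matrix(d[ax]), ax)
  stack
}

#' @rdname transform_4d
#' @param coeffs 4-D coefficient array produced by [transform_4d()].
#' @export
inverse_transform_4d <- function(coeffs) {
  d <- dim(coeffs)
  if (length(d) != 4L) stop_input("inverse_transform_4d expects a 4-D array")
  for (ax in 1:4) coeffs <- axis_apply(coeffs, t(dct_matrix(d[ax])), ax)
  coeffs
}

#' Separable orthonormal 3-D DCT (single-frame degeneracy)
#'
#' The 3-D transform used when only one time frame is present (a BM3D-style
#' group `N x N x |S|`): spatial DCTs followed by the group-axis DCT. With a
#' singleton temporal axis, [transform_4d()] reduces to this transform exactly.
#'
#' @param stack 3-D numeric array.
#' @return coefficient array of the same shape.
#' @export
transform_3d <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3L) stop_input("transform_3d expects a 3-D array")
  for (ax in 1:3) stack <- axis_apply(stack, dct_matrix(d[ax]), ax)
  stack
}

#' @rdname transform_3d
#' @param coeffs 3-D coefficient array produced by [transform_3d()].
#' @export
inverse_transform_3d <- function(coeffs) {
  d <- dim(coeffs)
  if (length(d) != 3L) stop_input("inverse_transform_3d expects a 3-D array")
  for (ax in 1:3) coeffs <- axis_apply(coeffs, t(dct_matrix(d[ax])), ax)
  coeffs
}
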