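#' Similarity transform (rotation, uniform scale, translation)
#'
#' The transform class used to register the imaging frame onto the barcoded
#' spot grid: a point `p = (x, y)` maps to `s * R(theta) %*% p + t`, with the
#' rotation taken counter-clockwise about the origin of the coordinate frame.
#' Coordinates are `x = column`, `y = row`, 0-based pixel centers.
#'
#' @param rotation_deg Rotation angle in degrees, counter-clockwise.
#' @param scale Uniform scale factor; must be positive. A negative-determinant
#'   (reflecting) similarity is represented via `reflect = TRUE`.
#' @param translation Numeric length-2, translation in the output units.
#' @param reflect If `TRUE`, the x axis is flipped before rotation.
#' @return An object of class `similarity_transform`.
#' @examples
#' tf <- similarity_transform(90, 1, c(0, 0))
#' transform_points(data.frame(x = 1, y = 0), tf) # (0, 1)
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1,
                                 translation = c(0, 0), reflect = FALSE) {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1,
            is.numeric(scale), length(scale) == 1,
            is.numeric(translation), length(translation) == 2)
  if (!is.finite(scale) || scale <= 0) {
    abort("`scale` must be a positive finite number.")
  }
  structure(
    list(rotation_deg = as.numeric(rotation_deg),
         scale = as.numeric(scale),
         translation = as.numeric(translation),
         reflect = isTRUE(reflect)),
    class = "similarity_transform"
  )
}

#' Affine transform from a 2x3 coefficient matrix
#'
#' Used for landmark-based alignment of adjacent sections. A point `(x, y)`
#' maps to `A %*% c(x, y) + b` where `A = m[, 1:2]` and `b = m[, 3]`.
#'
#' @param m Numeric 2x3 matrix; the 2x2 linear part must be nonsingular.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 3)) || !all(is.finite(m))) {
    abort("`m` must be a finite 2x3 numeric matrix.")
  }
  if (abs(det(m[, 1:2])) < .Machine$double.eps * 100) {
    abort("The linear part of the affine transform is singular.")
  }
  structure(list(m = m), class = "affine_transform")
}

#' Transform matrix (2x3) of a transform object
#' @param transform A `similarity_transform` or `affine_transform`.
#' @return A 2x3 numeric matrix `[A | b]`.
#' @export
transform_matrix <- function(transform) {
  if (inherits(transform, "affine_transform")) return(transform$m)
  stopifnot(inherits(transform, "similarity_transform"))
  th <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  F <- if (transform$reflect) diag(c(-1, 1)) else diag(2)
  A <- transform$scale * R %*% F
  cbind(A, transform$translation)
}

#' Apply a transform to points
#'
#' Exact matrix application; the first argument is a data frame with `x` and
#' `y` columns (returned with those columns replaced) or a 2-column matrix.
#'
#' @param points Data frame with numeric `x`, `y` columns, or an n x 2 matrix.
#' @param transform A `similarity_transform` or `affine_transform`.
#' @return Same shape as `points`, with transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  M <- transform_matrix(transform)
  if (is.data.frame(points)) {
    xy <- cbind(points$x, points$y)
    out <- xy %*% t(M[, 1:2]) + rep(M[, 3], each = nrow(xy))
    points$x <- out[, 1]
    points$y <- out[, 2]
    points
  } else {
    out <- points %*% t(M[, 1:2]) + rep(M[, 3], each = nrow(points))
    colnames(out) <- colnames(points)
    out
  }
}

#' Invert a transform
#' @param transform A `similarity_transform` or `affine_transform`.
#' @return The inverse transform, of the same class.
#' @export
invert_transform <- function(transform) {
  if (inherits(transform, "similarity_transform")) {
    if (transform$reflect) {
      # invert via the matrix form, refold into parameters
      M <- transform_matrix(transform)
      Ai <- solve(M[, 1:2])
      return(affine_transform(cbind(Ai, -Ai %*% M[, 3])))
    }
    s <- 1 / transform$scale
    th <- -transform$rotation_deg
    M <- transform_matrix(transform)
    Ai <- solve(M[, 1:2])
    t_inv <- -Ai %*% M[, 3]
    return(similarity_transform(th, s, as.numeric(t_inv)))
  }
  M <- transform_matrix(transform)
  Ai <- solve(M[, 1:2])
  affine_transform(cbind(Ai, -Ai %*% M[, 3]))
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param first,second Transform objects.
#' @return An `affine_transform` (or `similarity_transform` when both inputs
#'   are non-reflecting similarities).
#' @export
compose_transforms <- function(first, second) {
  M1 <- transform_matrix(first)
  M2 <- transform_matrix(second)
  A <- M2[, 1:2] %*% M1[, 1:2]
  b <- M2[, 1:2] %*% M1[, 3] + M2[, 3]
  if (inherits(first, "similarity_transform") &&
      inherits(second, "similarity_transform") &&
      !first$reflect && !second$reflect) {
    s <- first$scale * second$scale
    th <- first$rotation_deg + second$rotation_deg
    return(similarity_transform(((th + 180) %% 360) - 180, s, as.numeric(b)))
  }
  affine_transform(cbind(A, b))
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> rotation %.4f deg, scale %.6f, translation (%.4f, %.4f)%s\n",
    x$rotation_deg, x$scale, x$translation[1], x$translation[2],
    if (x$reflect) ", reflected" else ""))
  invisible(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(round(x$m, 6))
  invisible(x)
}

#' @rdname similarity_transform
#' @param x A `similarity_transform`.
#' @param ... Unused.
#' @export
tidy.similarity_transform <- function(x, ...) {
  tibble(term = c("rotation_deg", "scale", "tx", "ty"),
         estimate = c(x$rotation_deg, x$scale, x$translation))
}

#' @rdname affine_transform
#' @param x An `affine_transform`.
#' @param ... Unused.
#' @export
tidy.affine_transform <- function(x, ...) {
  tibble(term = c("a11", "a12", "a21", "a22", "tx", "ty"),
         estimate = c(x$m[1, 1], x$m[1, 2], x$m[2, 1], x$m[2, 2],
                      x$m[1, 3], x$m[2, 3]))
}

# YAML serialization ---------------------------------------------------------

#' Read / write transforms as YAML
#'
#' Similarity transforms are stored as `rotation_deg`, `scale`, `tx`, `ty`
#' (plus `reflect`); affine transforms as the six row-major coefficients.
#'
#' @param transform A transform object.
#' @param path File path.
#' @return `write_transform_yaml()` returns `path` invisibly;
#'   `read_transform_yaml()` returns the transform object.
#' @export
write_transform_yaml <- function(transform, path) {
  if (inherits(transform, "similarity_transform")) {
    obj <- list(type = "similarity",
                rotation_deg = transform$rotation_deg,
                scale = transform$scale,
                tx = transform$translation[1],
                ty = transform$translation[2],
                reflect = transform$reflect)
  } else {
    obj <- list(type = "affine", matrix = as.numeric(t(transform$m)))
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_transform_yaml
#' @export
read_transform_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (identical(obj$type, "similarity")) {
    similarity_transform(obj$rotation_deg, obj$scale, c(obj$tx, obj$ty),
                         reflect = isTRUE(obj$reflect))
  } else if (identical(obj$type, "affine")) {
    affine_transform(matrix(as.numeric(obj$matrix), 2, 3, byrow = TRUE))
  } else {
    abort(sprintf("Unknown transform type in '%s'.", path))
  }
}
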