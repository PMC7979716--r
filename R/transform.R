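#' Similarity transform between staining rounds
#'
#' Rigid-plus-scale (similarity) transform relating one staining round to
#' the reference round. Serial scans of the same physical slide are related
#' by translation, small rotation and (close to unit) scale; there is no
#' local tissue deformation between rounds, so a global similarity
#' transform is the registration model.
#'
#' Convention: image pixel centres sit at integer coordinates
#' `(x = column, y = row)`, origin top-left. A transform maps
#' reference-frame coordinates `p` to moving-frame coordinates:
#' `T(p) = s * R(theta) * (p - c) + c + (dx, dy)` where `c` is the image
#' centre. [warp_image()] resamples the moving image at `T(p)` so the
#' warped result lives in the reference frame.
#'
#' @param dx_px,dy_px translation in pixels.
#' @param rotation_deg rotation about the image centre, degrees.
#' @param scale uniform scale; a plausibility gate restricts it to
#'   `[0.9, 1.1]` (serial sections cannot rescale more than that).
#' @param score optional registration similarity score.
#' @return Object of class `round_transform`.
#' @export
round_transform <- function(dx_px = 0, dy_px = 0, rotation_deg = 0,
                            scale = 1, score = NA_real_) {
  stopifnot(is.finite(dx_px), is.finite(dy_px), is.finite(rotation_deg),
            is.finite(scale))
  if (scale < 0.9 || scale > 1.1)
    stop("implausible scale ", scale, " (must be in [0.9, 1.1])")
  structure(
    list(dx_px = as.numeric(dx_px), dy_px = as.numeric(dy_px),
         rotation_deg = as.numeric(rotation_deg),
         scale = as.numeric(scale), score = as.numeric(score)),
    class = "round_transform"
  )
}

#' @export
print.round_transform <- function(x, ...) {
  cat(sprintf(
    "round_transform: dx=%.3f px dy=%.3f px rot=%.4f deg scale=%.4f%s\n",
    x$dx_px, x$dy_px, x$rotation_deg, x$scale,
    if (is.finite(x$score)) sprintf(" score=%.4f", x$score) else ""))
  invisible(x)
}

is_identity_transform <- function(tf, tol = 1e-12) {
  abs(tf$dx_px) < tol && abs(tf$dy_px) < tol &&
    abs(tf$rotation_deg) < tol && abs(tf$scale - 1) < tol
}

#' Invert a similarity transform
#'
#' Returns the transform `S` with `S(T(p)) = p` about the same centre.
#'
#' @param tf a [round_transform()].
#' @return a [round_transform()].
#' @export
invert_transform <- function(tf) {
  th <- -tf$rotation_deg * pi / 180
  s <- 1 / tf$scale
  # inverse: p = s' R(-theta) (q - c - t) + c
  #        = s' R(-theta) (q - c) + c - s' R(-theta) t
  R <- rot_mat(-tf$rotation_deg)
  tinv <- -s * as.numeric(R %*% c(tf$dx_px, tf$dy_px))
  round_transform(tinv[1], tinv[2], -tf$rotation_deg, s)
}

rot_mat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a transform to coordinates
#'
#' Maps reference-frame pixel coordinates to moving-frame coordinates
#' under the [round_transform()] convention.
#'
#' @param tf a [round_transform()].
#' @param x,y coordinate vectors (pixels).
#' @param dim image dimension `c(nrow, ncol)` defining the rotation centre.
#' @return list with transformed `x`, `y`.
#' @export
apply_transform <- function(tf, x, y, dim) {
  cx <- (dim[2] + 1) / 2
  cy <- (dim[1] + 1) / 2
  R <- rot_mat(tf$rotation_deg) * tf$scale
  xs <- x - cx
  ys <- y - cy
  list(x = R[1, 1] * xs + R[1, 2] * ys + cx + tf$dx_px,
       y = R[2, 1] * xs + R[2, 2] * ys + cy + tf$dy_px)
}

#' Warp an image into the reference frame
#'
#' Resamples `img` at the transformed coordinates, i.e.
#' `out[r, c] = img(T(c, r))`. Bilinear interpolation for continuous maps
#' (OD), nearest-neighbour for masks/labels. Samples falling outside the
#' image get `bg`.
#'
#' @param img numeric matrix.
#' @param tf a [round_transform()].
#' @param filter `"bilinear"` or `"nearest"`.
#' @param bg fill value for out-of-bounds samples.
#' @return matrix of the same dimension as `img`.
#' @export
warp_image <- function(img, tf, filter = c("bilinear", "nearest"), bg = 0) {
  filter <- match.arg(filter)
  d <- dim(img)
  if (is_identity_transform(tf)) return(img)
  # target grid coordinates (pixel centres)
  xs <- rep(seq_len(d[2]), each = d[1])
  ys <- rep(seq_len(d[1]), times = d[2])
  src <- apply_transform(tf, xs, ys, d)
  out <- matrix(bg, d[1], d[2])
  if (filter == "nearest") {
    xi <- round(src$x); yi <- round(src$y)
    ok <- xi >= 1 & xi <= d[2] & yi >= 1 & yi <= d[1]
    out[cbind(ys[ok], xs[ok])] <- img[cbind(yi[ok], xi[ok])]
  } else {
    x0 <- floor(src$x); y0 <- floor(src$y)
    fx <- src$x - x0;   fy <- src$y - y0
    ok <- x0 >= 1 & x0 + 1 <= d[2] & y0 >= 1 & y0 + 1 <= d[1]
    if (any(ok)) {
      x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
      i00 <- img[cbind(y0k, x0k)]
      i01 <- img[cbind(y0k, x0k + 1)]
      i10 <- img[cbind(y0k + 1, x0k)]
      i11 <- img[cbind(y0k + 1, x0k + 1)]
      val <- i00 * (1 - fxk) * (1 - fyk) + i01 * fxk * (1 - fyk) +
        i10 * (1 - fxk) * fyk + i11 * fxk * fyk
      out[cbind(ys[ok], xs[ok])] <- val
    }
  }
  out
}

#' Footprint of a warped image
#'
#' Boolean matrix marking pixels of the reference frame whose (bilinear)
#' sample lies fully inside the moving image — the region where warped
#' values are valid.
#'
#' @inheritParams warp_image
#' @return logical matrix.
#' @export
warp_footprint <- function(img, tf) {
  d <- dim(img)
  xs <- rep(seq_len(d[2]), each = d[1])
  ys <- rep(seq_len(d[1]), times = d[2])
  src <- apply_transform(tf, xs, ys, d)
  ok <- src$x >= 1 & src$x <= d[2] & src$y >= 1 & src$y <= d[1]
  matrix(ok, d[1], d[2])
}
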