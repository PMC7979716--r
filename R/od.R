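#' Stain basis for two-colour deconvolution
#'
#' Unit optical-density (OD) colour vectors for the chromogen and the
#' hematoxylin counterstain. Chromogenic IHC with a brown chromogen on a
#' blue nuclear counterstain is a two-stain problem: per pixel, stain
#' amounts add linearly in OD (Beer-Lambert), so the RGB OD vector is a
#' non-negative combination of the two basis vectors and can be unmixed by
#' least squares.
#'
#' The published Ruifrok-Johnston vectors are used for DAB and AEC; either
#' can be selected by name, or an arbitrary 3-vector supplied.
#'
#' @param chromogen `"DAB"`, `"AEC"`, or a numeric length-3 OD vector.
#' @param hematoxylin `"H"` (published vector) or a numeric length-3 OD
#'   vector.
#' @return Object of class `stain_basis`: list with unit-norm
#'   `chromogen_od_vector` and `hematoxylin_od_vector`.
#' @examples
#' b <- stain_basis()
#' sum(b$chromogen_od_vector^2)  # 1
#' @export
stain_basis <- function(chromogen = "DAB", hematoxylin = "H") {
  vectors <- list(
    DAB = c(0.268, 0.570, 0.776),
    AEC = c(0.2743, 0.6796, 0.6803),
    H   = c(0.650, 0.704, 0.286)
  )
  pick <- function(x) {
    if (is.character(x)) {
      x <- match.arg(toupper(x), names(vectors))
      v <- vectors[[x]]
    } else {
      v <- as.numeric(x)
      if (length(v) != 3L || any(!is.finite(v)) || all(v == 0))
        stop("stain vector must be a finite non-zero length-3 numeric")
    }
    v / sqrt(sum(v^2))
  }
  b <- structure(
    list(chromogen_od_vector = pick(chromogen),
         hematoxylin_od_vector = pick(hematoxylin)),
    class = "stain_basis"
  )
  validate_stain_basis(b)
  b
}

validate_stain_basis <- function(basis) {
  stopifnot(inherits(basis, "stain_basis"))
  ang <- basis_angle_deg(basis)
  if (ang <= 10)
    stop("near-collinear stain basis: angle ", format(ang, digits = 4),
         " deg <= 10 deg")
  invisible(basis)
}

basis_angle_deg <- function(basis) {
  ct <- sum(basis$chromogen_od_vector * basis$hematoxylin_od_vector)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Convert 8-bit RGB intensities to optical density
#'
#' Beer-Lambert conversion `OD_c = -log10((I_c + 1) / (bg_c + 1))` per
#' channel, clipped to `[0, od_max]`. The +1 pseudo-intensity keeps black
#' pixels finite; they clip to `od_max`.
#'
#' @param rgb H x W x 3 array of intensities in 0..255 (numeric or integer).
#' @param background per-channel background (white) intensity, length 1 or
#'   3. Default: per-channel 99th percentile of the image, a robust white
#'   estimate when no calibration target is available.
#' @param od_max upper OD clip (default 3, roughly the dynamic range of an
#'   8-bit scanner).
#' @return H x W x 3 array of OD values in `[0, od_max]`.
#' @export
rgb_to_od <- function(rgb, background = NULL, od_max = 3) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (is.null(background)) {
    background <- apply(rgb, 3, stats::quantile, probs = 0.99, names = FALSE)
  }
  background <- rep_len(as.numeric(background), 3L)
  if (any(background <= 0)) stop("background intensity must be positive")
  od <- rgb
  for (ch in 1:3) {
    od[, , ch] <- -log10((rgb[, , ch] + 1) / (background[ch] + 1))
  }
  od[od < 0] <- 0
  od[od > od_max] <- od_max
  od
}

#' Convert optical density back to RGB intensities
#'
#' Inverse of [rgb_to_od()]: `I_c = (bg_c + 1) * 10^-OD_c - 1`, clipped to
#' 0..255. Values are returned as doubles; quantize with `round()` for an
#' 8-bit image.
#'
#' @param od H x W x 3 OD array.
#' @param background per-channel background intensity (length 1 or 3).
#' @return H x W x 3 double array in 0..255.
#' @export
od_to_rgb <- function(od, background = 255) {
  stopifnot(length(dim(od)) == 3L, dim(od)[3] == 3L)
  background <- rep_len(as.numeric(background), 3L)
  out <- od
  for (ch in 1:3) {
    out[, , ch] <- (background[ch] + 1) * 10^(-od[, , ch]) - 1
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Unmix a two-stain OD image into chromogen and hematoxylin maps
#'
#' Least-squares projection of each pixel's OD 3-vector onto the two basis
#' vectors (normal equations of the 3 x 2 system); negative coefficients
#' are clipped to zero and the residual (off-plane colour) is discarded.
#'
#' @param od H x W x 3 OD array (from [rgb_to_od()]).
#' @param basis a [stain_basis()].
#' @param od_max upper clip for the returned maps.
#' @return List of class `od_maps` with `chromogen_od` and
#'   `hematoxylin_od` H x W matrices, non-negative and NaN-free.
#' @export
separate_stains <- function(od, basis, od_max = 3) {
  validate_stain_basis(basis)
  stopifnot(length(dim(od)) == 3L, dim(od)[3] == 3L)
  M <- cbind(basis$chromogen_od_vector, basis$hematoxylin_od_vector)
  # pseudo-inverse of the 3x2 mixing matrix; 2x3
  P <- solve(crossprod(M), t(M))
  d <- dim(od)[1:2]
  flat <- matrix(od, ncol = 3L)            # n x 3
  coefs <- flat %*% t(P)                   # n x 2
  coefs[coefs < 0] <- 0
  coefs[coefs > od_max] <- od_max
  structure(
    list(chromogen_od = matrix(coefs[, 1L], d[1], d[2]),
         hematoxylin_od = matrix(coefs[, 2L], d[1], d[2])),
    class = "od_maps"
  )
}

#' Synthesize a two-stain OD image from coefficient maps
#'
#' Forward model inverted by [separate_stains()]: each pixel's OD vector is
#' `chromogen * v_c + hematoxylin * v_h`.
#'
#' @param chromogen_od,hematoxylin_od H x W coefficient matrices.
#' @param basis a [stain_basis()].
#' @return H x W x 3 OD array.
#' @export
synthesize_od <- function(chromogen_od, hematoxylin_od, basis) {
  validate_stain_basis(basis)
  stopifnot(all(dim(chromogen_od) == dim(hematoxylin_od)))
  d <- dim(chromogen_od)
  od <- array(0, c(d, 3L))
  for (ch in 1:3) {
    od[, , ch] <- chromogen_od * basis$chromogen_od_vector[ch] +
      hematoxylin_od * basis$hematoxylin_od_vector[ch]
  }
  od
}
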