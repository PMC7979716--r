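#' @title Rigid registration of staining rounds
#' @description
#' The counterstain (hematoxylin) is repeated in every staining round, so
#' registration is estimated on the hematoxylin OD maps: coarse search by
#' phase correlation over a rotation grid on a downsampled pyramid, then
#' local refinement of the normalised cross-correlation (NCC) by
#' Nelder-Mead at increasing resolution.
#' @name registration
NULL

# mean-pool downsample by integer factor (crops to a multiple)
downsample <- function(img, f) {
  if (f <= 1L) return(img)
  d <- dim(img)
  nr <- (d[1] %/% f) * f
  nc <- (d[2] %/% f) * f
  x <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  x <- array(x, c(f, nr %/% f, f, nc %/% f))
  colMeans(aperm(x, c(1, 3, 2, 4)), dims = 2)
}

hann2d <- function(d) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1))
  outer(wy, wx)
}

# candidate translations (dx, dy) such that
# warp_image(moving, round_transform(dx, dy)) matches fixed. Returns the
# top_k separated peaks of the phase-correlation surface (repetitive
# content — e.g. regularly packed tumour nuclei — produces lattice-alias
# side peaks, so the final choice is made downstream by NCC), each with
# parabolic sub-pixel refinement.
phase_correlate <- function(fixed, moving, window = TRUE, top_k = 12L) {
  d <- dim(fixed)
  stopifnot(all(d == dim(moving)))
  w <- if (window) hann2d(d) else 1
  Ff <- stats::fft((fixed - mean(fixed)) * w)
  Fm <- stats::fft((moving - mean(moving)) * w)
  R <- Ff * Conj(Fm)
  mag <- Mod(R)
  # whitened (phase-only) surface: sharp peaks, but repetitive content
  # produces lattice aliases; plain cross-correlation: broad but
  # unambiguous low-frequency peak. Candidates come from both.
  cc <- Re(stats::fft(R / (mag + 1e-12), inverse = TRUE)) / length(R)
  cc_plain <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  sep2 <- function(a, b, n) {
    dd <- abs(a - b)
    pmin(dd, n - dd)^2
  }
  top_peaks <- function(surface, k) {
    ord <- order(surface, decreasing = TRUE)[
      seq_len(min(400L, length(surface)))]
    pk <- arrayInd(ord, d)
    keep <- integer(0)
    for (i in seq_len(nrow(pk))) {
      if (length(keep) >= k) break
      if (!length(keep) ||
          all(sep2(pk[i, 1], pk[keep, 1], d[1]) +
                sep2(pk[i, 2], pk[keep, 2], d[2]) >= 16))
        keep <- c(keep, i)
    }
    pk[keep, , drop = FALSE]
  }
  peaks <- rbind(top_peaks(cc, top_k), top_peaks(cc_plain, top_k))
  signed <- function(u, n) ifelse(u > n / 2, u - n, u)
  lapply(seq_len(nrow(peaks)), function(i) {
    peak <- peaks[i, ]
    sub <- function(along) {
      n <- d[along]
      at <- function(k) {
        k <- ((k - 1) %% n) + 1
        if (along == 1L) cc[k, peak[2]] else cc[peak[1], k]
      }
      c0 <- at(peak[along]); cm <- at(peak[along] - 1L)
      cp <- at(peak[along] + 1L)
      den <- cm - 2 * c0 + cp
      if (abs(den) < 1e-15) 0
      else pmax(-0.5, pmin(0.5, 0.5 * (cm - cp) / den))
    }
    # the correlation peak sits at u = -t (mod N) for content shifted by
    # +t in our sampling convention, hence the negation
    list(dx = -(signed(peak[2] - 1L, d[2]) + sub(2L)),
         dy = -(signed(peak[1] - 1L, d[1]) + sub(1L)),
         peak = cc[peak[1], peak[2]])
  })
}

# NCC between fixed and the warp of moving, over the warped footprint
ncc_score <- function(fixed, moving, tf) {
  w <- warp_image(moving, tf)
  fp <- warp_footprint(moving, tf)
  if (sum(fp) < 16) return(-1)
  a <- fixed[fp]; b <- w[fp]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-1)
  stats::cor(a, b)
}

#' Register one image to a fixed reference
#'
#' Estimates the similarity transform (translation + rotation, unit scale)
#' that warps `moving` onto `fixed`. Coarse stage: phase correlation on a
#' mean-pooled pyramid over a rotation grid; refinement: Nelder-Mead on the
#' NCC at half, then full working resolution.
#'
#' @param fixed,moving numeric matrices (hematoxylin OD maps).
#' @param max_rotation_deg half-width of the rotation search grid.
#' @param rotation_step_deg coarse grid step.
#' @param refine_full_res add a final refinement pass at half/native
#'   resolution (slower; the default quarter-resolution refinement is
#'   already accurate to well under 0.1 px on slide-like content).
#' @return a [round_transform()] with its NCC `score` filled in.
#' @export
register_pair <- function(fixed, moving, max_rotation_deg = 3.5,
                          rotation_step_deg = 0.5, refine_full_res = FALSE) {
  d <- dim(fixed)
  stopifnot(all(d == dim(moving)))
  f_coarse <- max(1L, 2L^floor(log2(min(d) / 128)))
  fc <- downsample(fixed, f_coarse)
  mc <- downsample(moving, f_coarse)
  rots <- seq(-max_rotation_deg, max_rotation_deg, by = rotation_step_deg)
  best <- NULL
  for (r in rots) {
    mrot <- warp_image(mc, round_transform(0, 0, r))
    for (pc in phase_correlate(fc, mrot)) {
      # a shift found on the pre-rotated image composes with the rotation
      # as moving(R(p + t - c) + c) = moving(R(p - c) + c + R t), so the
      # combined translation is R %*% t
      tt <- rot_mat(r) %*% c(pc$dx, pc$dy) * f_coarse
      sc <- ncc_score(fc, mc, round_transform(tt[1] / f_coarse,
                                              tt[2] / f_coarse, r))
      if (is.null(best) || sc > best$sc)
        best <- list(tf = round_transform(tt[1], tt[2], r), sc = sc)
    }
  }
  refine <- function(tf, fx, mv, fac, maxit) {
    obj <- function(par) {
      -ncc_score(fx, mv, round_transform(par[1], par[2], par[3]))
    }
    st <- c(tf$dx_px / fac, tf$dy_px / fac, tf$rotation_deg)
    op <- stats::optim(st, obj, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-9))
    round_transform(op$par[1] * fac, op$par[2] * fac, op$par[3],
                    score = -op$value)
  }
  levels <- unique(c(max(1L, f_coarse %/% 2L),
                     if (refine_full_res) c(2L, 1L)))
  levels <- levels[levels <= max(levels[1], 1L)]
  tf <- best$tf
  for (k in seq_along(levels)) {
    f <- levels[k]
    tf <- refine(tf, downsample(fixed, f), downsample(moving, f), f,
                 if (k == 1L) 200 else 60)
  }
  tf
}

#' Register all staining rounds to a reference round
#'
#' Registration runs on the hematoxylin OD maps, shared across rounds
#' because the counterstain is repeated in each staining cycle. The
#' reference round receives the identity transform.
#'
#' @param rounds list of [stain_round()] objects (all six markers).
#' @param basis a [stain_basis()] used to extract hematoxylin OD.
#' @param reference_marker marker name of the fixed round (default
#'   `"Foxp3"`, the first round in the staining order).
#' @param min_score NCC floor; an optimum below it raises a
#'   `ngiplex_registration_failure` condition carrying the best score.
#' @param ... passed to [register_pair()].
#' @return named list of [round_transform()], one per round, in input
#'   order.
#' @export
register_rounds <- function(rounds, basis = stain_basis(),
                            reference_marker = "Foxp3", min_score = 0.2,
                            ...) {
  stopifnot(length(rounds) >= 2L)
  markers <- vapply(rounds, function(r) r$marker_name, character(1))
  if (!reference_marker %in% markers)
    stop("reference marker ", reference_marker, " not among rounds")
  hema <- lapply(rounds, function(r) {
    separate_stains(rgb_to_od(r$rgb_pixels), basis)$hematoxylin_od
  })
  iref <- match(reference_marker, markers)
  out <- vector("list", length(rounds))
  names(out) <- markers
  for (i in seq_along(rounds)) {
    if (i == iref) {
      tf <- round_transform()
      tf$score <- 1
      out[[i]] <- tf
    } else {
      tf <- register_pair(hema[[iref]], hema[[i]], ...)
      if (is.finite(tf$score) && tf$score < min_score) {
        cond <- structure(
          class = c("ngiplex_registration_failure", "error", "condition"),
          list(message = sprintf(
            "registration of round '%s' failed: best NCC %.3f < floor %.3f",
            markers[i], tf$score, min_score),
            call = sys.call(-1), score = tf$score, marker = markers[i]))
        stop(cond)
      }
      out[[i]] <- tf
    }
  }
  out
}
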