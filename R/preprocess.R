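# Input preparation: the vessel branch consumes the CLAHE-equalized green
# channel; the A/V branch consumes the raw RGB image.  Training uses random
# aligned patch crops with right-angle rotation and Gaussian-noise
# augmentation; inference tiles each image in raster order and stitches the
# per-patch outputs back together exactly.

#' Contrast Limited Adaptive Histogram Equalization
#'
#' Classic CLAHE on a single-channel image: the image is divided into a grid
#' of tiles, each tile's histogram is clipped at `clip` times the uniform
#' bin count (the excess redistributed uniformly), and per-tile CDF mappings
#' are bilinearly interpolated between tile centers.
#'
#' @param x numeric matrix in [0, 1]
#' @param clip clip limit as a multiple of the uniform histogram height
#' @param grid c(rows, cols) tile grid
#' @param nbins histogram bins
#' @return numeric matrix in [0, 1]
#' @export
clahe <- function(x, clip = 2.0, grid = c(8, 8), nbins = 256) {
  h <- nrow(x); w <- ncol(x)
  gr <- grid[1]; gc <- grid[2]
  bin <- pmin(pmax(floor(x * nbins) + 1L, 1L), nbins)

  # tile index of each row/column (0-based), tiles as even as possible
  tr <- pmin(floor((seq_len(h) - 1) / (h / gr)), gr - 1)
  tc <- pmin(floor((seq_len(w) - 1) / (w / gc)), gc - 1)

  # per-tile clipped-histogram CDF mappings, columns indexed by tile id
  maps <- matrix(0, nbins, gr * gc)
  for (i in 0:(gr - 1)) {
    for (j in 0:(gc - 1)) {
      b <- bin[tr == i, tc == j]
      hist_ <- tabulate(b, nbins)
      limit <- max(1, clip * length(b) / nbins)
      excess <- sum(pmax(hist_ - limit, 0))
      hist_ <- pmin(hist_, limit) + excess / nbins
      cdf <- cumsum(hist_)
      maps[, i + gr * j + 1L] <- (cdf - cdf[1]) / max(cdf[nbins] - cdf[1], 1e-12)
    }
  }

  # fractional tile coordinate of each pixel relative to tile centers
  centers_r <- (0:(gr - 1) + 0.5) * h / gr
  centers_c <- (0:(gc - 1) + 0.5) * w / gc
  fr <- (seq_len(h) - 0.5 - centers_r[1]) / (h / gr)
  fc <- (seq_len(w) - 0.5 - centers_c[1]) / (w / gc)
  fr <- pmin(pmax(fr, 0), gr - 1); fc <- pmin(pmax(fc, 0), gc - 1)
  r0 <- floor(fr); wr <- fr - r0; r1 <- pmin(r0 + 1, gr - 1)
  c0 <- floor(fc); wc <- fc - c0; c1 <- pmin(c0 + 1, gc - 1)

  R0 <- matrix(r0, h, w); R1 <- matrix(r1, h, w)
  C0 <- matrix(c0, h, w, byrow = TRUE); C1 <- matrix(c1, h, w, byrow = TRUE)
  WR <- matrix(wr, h, w); WC <- matrix(wc, h, w, byrow = TRUE)
  look <- function(R, C) maps[cbind(as.vector(bin), as.vector(R + gr * C + 1))]
  out <- (1 - WR) * (1 - WC) * look(R0, C0) + (1 - WR) * WC * look(R0, C1) +
    WR * (1 - WC) * look(R1, C0) + WR * WC * look(R1, C1)
  matrix(out, h, w)
}

#' Vessel-branch input: CLAHE-equalized green channel in [0, 1]
#'
#' The artery/vein branch uses the raw RGB image; this single channel feeds
#' only the vessel-extraction network.
#' @param image H x W x 3 array on the 0..255 scale
#' @param clip,grid CLAHE parameters
#' @return H x W x 1 array with values in [0, 1]
#' @export
vessel_input_channels <- function(image, clip = 2.0, grid = c(8, 8)) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("vessel_input_channels() expects a 3-channel image, got dim ",
         paste(d, collapse = "x"))
  }
  g <- clahe(image[, , 2] / 255, clip = clip, grid = grid)
  array(g, dim = c(d[1], d[2], 1L))
}

crop2 <- function(x, r, c, p) {
  if (is.null(x)) return(NULL)
  if (length(dim(x)) == 3L) x[r:(r + p - 1), c:(c + p - 1), , drop = FALSE]
  else x[r:(r + p - 1), c:(c + p - 1), drop = FALSE]
}

#' Randomly crop aligned square patches from a sample
#'
#' The identical crop window is applied to the image and to whichever labels
#' are present; windows are uniform over all valid positions.
#'
#' @param sample a [fundus_sample()]
#' @param n number of patches
#' @param patch patch side, pixels (default 256 as used at full scale)
#' @param rng_seed seed for reproducible cropping
#' @return list of crops, each a list with `image`, `mask`, `av`, `origin`
#' @export
random_patches <- function(sample, n, patch = 256, rng_seed = 1L) {
  d <- dim(sample$image)
  if (d[1] < patch || d[2] < patch) {
    stop(sprintf("image %dx%d is smaller than the %d-pixel patch; resize first",
                 d[1], d[2], patch))
  }
  with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      r <- sample.int(d[1] - patch + 1L, 1L)
      c <- sample.int(d[2] - patch + 1L, 1L)
      list(image = crop2(sample$image, r, c, patch),
           mask = crop2(sample$vessel_mask, r, c, patch),
           av = crop2(sample$av_labels, r, c, patch),
           origin = c(r, c))
    })
  })
}

# rotate a matrix (or each channel of an H x W x C array) by k * 90 degrees
# clockwise; k = 2 twice is the identity
rot90k <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  if (length(dim(x)) == 3L) {
    dims <- if (k %% 2L == 1L) dim(x)[c(2, 1, 3)] else dim(x)
    out <- array(0, dim = dims)
    for (ch in seq_len(dim(x)[3])) out[, , ch] <- rot90k(x[, , ch], k)
    storage.mode(out) <- storage.mode(x)
    return(out)
  }
  for (i in seq_len(k)) x <- t(x[nrow(x):1, , drop = FALSE])
  x
}

#' Rotate and add noise to an aligned patch crop
#'
#' One rotation drawn uniformly from 0/90/180/270 degrees is applied jointly
#' to the image and labels; zero-mean Gaussian noise with sd drawn uniformly
#' from [0, `noise_sd_max`] (in normalized [0,1] intensity) is then added to
#' the image only, which is clipped back to the valid range.  Labels never
#' receive noise, so image/label alignment is exact.
#'
#' @param crop a crop as returned by [random_patches()]
#' @param rng_seed seed
#' @param noise_sd_max upper bound of the noise sd in normalized intensity
#' @return a crop of the same structure
#' @export
augment <- function(crop, rng_seed = 1L, noise_sd_max = 0.02) {
  with_seed(rng_seed, {
    k <- sample.int(4L, 1L) - 1L
    sd_ <- stats::runif(1, 0, noise_sd_max)
    img <- rot90k(crop$image, k)
    img <- img + stats::rnorm(length(img), sd = sd_ * 255)
    img <- pmin(pmax(img, 0), 255)
    dim(img) <- dim(rot90k(crop$image, k))
    list(image = img,
         mask = if (is.null(crop$mask)) NULL else rot90k(crop$mask, k),
         av = if (is.null(crop$av)) NULL else rot90k(crop$av, k),
         origin = crop$origin)
  })
}

#' Tile an array into non-overlapping patches in raster order
#'
#' The array is zero-padded at the bottom/right to a multiple of `patch`;
#' patches cover the padded extent exactly once, ordered rows-first.
#'
#' @param image_like matrix or H x W x C array
#' @param patch patch side in pixels
#' @return list with `grid` (a `patch_grid`: image_size, patch_size, origins,
#'   pad) and `patches` (list of patch arrays)
#' @export
tile <- function(image_like, patch) {
  d <- dim(image_like)
  h <- d[1]; w <- d[2]
  ph <- ceiling(h / patch) * patch
  pw <- ceiling(w / patch) * patch
  pad <- c(bottom = ph - h, right = pw - w)
  if (length(d) == 3L) {
    big <- array(0, dim = c(ph, pw, d[3]))
    big[1:h, 1:w, ] <- image_like
  } else {
    big <- matrix(0, ph, pw)
    big[1:h, 1:w] <- image_like
  }
  origins <- as.matrix(expand.grid(
    col = seq(1, pw, by = patch), row = seq(1, ph, by = patch)))[, c("row", "col"), drop = FALSE]
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    crop2(big, origins[i, 1], origins[i, 2], patch)
  })
  grid <- structure(list(image_size = c(h, w), patch_size = patch,
                         origins = origins, pad = pad),
                    class = "patch_grid")
  list(grid = grid, patches = patches)
}

#' Reassemble patch outputs produced over a [tile()] grid
#'
#' Places each patch at its origin and crops away the padding, so
#' `stitch(tile(x)$grid, tile(x)$patches)` returns `x` exactly.
#'
#' @param grid a `patch_grid` from [tile()]
#' @param patch_outputs list of patch-sized arrays in grid order (the channel
#'   count may differ from the tiled input's)
#' @return array of the original spatial size
#' @export
stitch <- function(grid, patch_outputs) {
  stopifnot(inherits(grid, "patch_grid"))
  n <- nrow(grid$origins)
  if (length(patch_outputs) != n) {
    stop(sprintf("expected %d patches, got %d", n, length(patch_outputs)))
  }
  p <- grid$patch_size
  d1 <- dim(patch_outputs[[1]])
  if (any(d1[1:2] != p)) {
    stop(sprintf("patch outputs must be %dx%d, got %dx%d", p, p, d1[1], d1[2]))
  }
  ph <- grid$image_size[1] + grid$pad[["bottom"]]
  pw <- grid$image_size[2] + grid$pad[["right"]]
  nc <- if (length(d1) == 3L) d1[3] else 1L
  big <- array(0, dim = c(ph, pw, nc))
  for (i in seq_len(n)) {
    r <- grid$origins[i, 1]; c <- grid$origins[i, 2]
    po <- patch_outputs[[i]]
    if (length(dim(po)) == 2L) dim(po) <- c(p, p, 1L)
    big[r:(r + p - 1), c:(c + p - 1), ] <- po
  }
  out <- big[seq_len(grid$image_size[1]), seq_len(grid$image_size[2]), , drop = FALSE]
  if (length(d1) == 2L) out <- out[, , 1]
  out
}

# bilinear resize of a matrix to (th, tw), align_corners = FALSE convention
resize_bilinear <- function(x, th, tw) {
  h <- nrow(x); w <- ncol(x)
  sr <- (seq_len(th) - 0.5) * h / th - 0.5
  sc <- (seq_len(tw) - 0.5) * w / tw - 0.5
  r0 <- pmin(pmax(floor(sr), 0), h - 1); r1 <- pmin(r0 + 1, h - 1); tr <- sr - floor(sr)
  tr[sr < 0] <- 0; tr[sr > h - 1] <- 0
  c0 <- pmin(pmax(floor(sc), 0), w - 1); c1 <- pmin(c0 + 1, w - 1); tc <- sc - floor(sc)
  tc[sc < 0] <- 0; tc[sc > w - 1] <- 0
  a <- x[r0 + 1, c0 + 1, drop = FALSE] * (1 - tr) + x[r1 + 1, c0 + 1, drop = FALSE] * tr
  b <- x[r0 + 1, c1 + 1, drop = FALSE] * (1 - tr) + x[r1 + 1, c1 + 1, drop = FALSE] * tr
  sweep(a, 2, 1 - tc, `*`) + sweep(b, 2, tc, `*`)
}

resize_nearest <- function(x, th, tw) {
  h <- nrow(x); w <- ncol(x)
  ri <- pmin(pmax(ceiling((seq_len(th) - 0.5) * h / th), 1), h)
  ci <- pmin(pmax(ceiling((seq_len(tw) - 0.5) * w / tw), 1), w)
  x[ri, ci, drop = FALSE]
}

#' Resize a sample; labels stay categorical
#'
#' The image is resized with bilinear interpolation; the vessel mask and A/V
#' labels with nearest-neighbor so no new label values can appear.
#'
#' @param sample a [fundus_sample()]
#' @param target c(height, width)
#' @return a resized [fundus_sample()]
#' @export
resize_sample <- function(sample, target) {
  stopifnot(all(target >= 1))
  th <- target[1]; tw <- target[2]
  d <- dim(sample$image)
  if (th == d[1] && tw == d[2]) return(sample)
  img <- array(0, dim = c(th, tw, 3L))
  for (ch in 1:3) img[, , ch] <- resize_bilinear(sample$image[, , ch], th, tw)
  fundus_sample(
    img,
    if (is.null(sample$vessel_mask)) NULL else resize_nearest(sample$vessel_mask, th, tw),
    if (is.null(sample$av_labels)) NULL else resize_nearest(sample$av_labels, th, tw),
    sample$sample_id
  )
}
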