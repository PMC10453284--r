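# Reading and writing fundus samples.
#
# On-disk conventions (DRIVE-style): vessel masks are grayscale images where
# any nonzero intensity marks a vessel pixel; artery/vein label maps are RGB
# images with pure red = artery, pure blue = vein, pure green = uncertain and
# black = background.  In memory, images are numeric H x W x 3 arrays on the
# 0..255 scale and label maps are integer H x W arrays of class codes.

#' Artery/vein label codes
#'
#' Integer codes used in `av_labels` arrays: background 0, artery 1, vein 2,
#' uncertain 3.
#' @export
AV_BACKGROUND <- 0L
#' @rdname AV_BACKGROUND
#' @export
AV_ARTERY <- 1L
#' @rdname AV_BACKGROUND
#' @export
AV_VEIN <- 2L
#' @rdname AV_BACKGROUND
#' @export
AV_UNCERTAIN <- 3L

# canonical label colors, one row per code 0..3
.av_colors <- rbind(
  BACKGROUND = c(0, 0, 0),
  ARTERY     = c(255, 0, 0),
  VEIN       = c(0, 0, 255),
  UNCERTAIN  = c(0, 255, 0)
)

#' Read an image file as an H x W x 3 array on the 0..255 scale
#'
#' PNG and JPEG are supported (no TIFF/GIF codec is available offline).
#' Grayscale images are replicated to three channels; alpha is dropped.
#' @param path image file
#' @return numeric array, dim c(H, W, 3), values 0..255
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "' (PNG/JPEG supported): ", path)
  )
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an H x W x 3 (0..255) or H x W ([0,1] grayscale) array as PNG
#' @param img array as produced by [read_image()] (or a matrix in [0,1])
#' @param path output file
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) == 3L) img <- img / 255
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

decode_av <- function(rgb, tol = 10, path = "<array>") {
  d <- dim(rgb)
  n <- d[1] * d[2]
  m <- matrix(rgb, nrow = n)  # n x 3
  codes <- rep(NA_integer_, n)
  for (code in 0:3) {
    cc <- .av_colors[code + 1L, ]
    hit <- abs(m[, 1] - cc[1]) <= tol & abs(m[, 2] - cc[2]) <= tol &
      abs(m[, 3] - cc[3]) <= tol
    codes[hit & is.na(codes)] <- code
  }
  if (anyNA(codes)) {
    bad <- m[is.na(codes), , drop = FALSE]
    ex <- bad[1, ]
    stop(sprintf(paste0(
      "unrecognized label color(s) in A/V image %s: %d pixel(s) outside +-%d of the ",
      "canonical colors (first offender RGB = [%d, %d, %d])"),
      path, nrow(bad), tol, ex[1], ex[2], ex[3]))
  }
  matrix(codes, d[1], d[2])
}

decode_mask <- function(rgb) {
  d <- dim(rgb)
  mask <- matrix(0L, d[1], d[2])
  mask[pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3]) > 0] <- 1L
  mask
}

#' Read a fundus sample (image plus optional vessel mask and A/V labels)
#'
#' Label decoding is exact up to a per-channel tolerance of +-10 intensity
#' levels: pure red maps to artery, pure blue to vein, pure green to
#' uncertain and black to background; any other color is an error.  Vessel
#' masks decode any nonzero intensity as vessel.  When both labels are
#' present the mask is completed with `mask | (av != background)` so that
#' every labeled vessel pixel is also a mask pixel.
#'
#' @param image_path RGB fundus photograph (PNG/JPEG)
#' @param mask_path optional binary vessel mask image
#' @param av_path optional color-coded artery/vein label image
#' @param sample_id identifier; defaults to the image file stem
#' @return a `fundus_sample`: list with `image` (H x W x 3, 0..255),
#'   `vessel_mask` (H x W, 0/1 or NULL), `av_labels` (H x W codes or NULL),
#'   `sample_id`
#' @export
read_sample <- function(image_path, mask_path = NULL, av_path = NULL,
                        sample_id = NULL) {
  img <- read_image(image_path)
  d <- dim(img)[1:2]
  mask <- NULL
  av <- NULL
  if (!is.null(mask_path)) {
    mrgb <- read_image(mask_path)
    md <- dim(mrgb)[1:2]
    if (!identical(md, d)) {
      stop(sprintf("vessel mask size %dx%d does not match image size %dx%d",
                   md[1], md[2], d[1], d[2]))
    }
    mask <- decode_mask(mrgb)
  }
  if (!is.null(av_path)) {
    argb <- read_image(av_path)
    ad <- dim(argb)[1:2]
    if (!identical(ad, d)) {
      stop(sprintf("A/V label size %dx%d does not match image size %dx%d",
                   ad[1], ad[2], d[1], d[2]))
    }
    av <- decode_av(argb, path = av_path)
    if (is.null(mask)) mask <- matrix(0L, d[1], d[2])
    mask[av != AV_BACKGROUND] <- 1L
  }
  fundus_sample(img, mask, av,
                sample_id %||% tools::file_path_sans_ext(basename(image_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a fundus sample from in-memory arrays
#' @param image H x W x 3 array, 0..255
#' @param vessel_mask optional H x W 0/1 matrix
#' @param av_labels optional H x W matrix of label codes
#' @param sample_id identifier string
#' @export
fundus_sample <- function(image, vessel_mask = NULL, av_labels = NULL,
                          sample_id = "sample") {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3] == 3L)
  for (lab in list(vessel_mask, av_labels)) {
    if (!is.null(lab) && !identical(dim(lab)[1:2], d[1:2])) {
      stop(sprintf("label size %dx%d does not match image size %dx%d",
                   dim(lab)[1], dim(lab)[2], d[1], d[2]))
    }
  }
  if (!is.null(av_labels) && !is.null(vessel_mask)) {
    vessel_mask[av_labels != AV_BACKGROUND] <- 1L
  }
  structure(list(image = image, vessel_mask = vessel_mask,
                 av_labels = av_labels, sample_id = sample_id),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fundus_sample '%s'> %dx%d, mask: %s, A/V labels: %s\n",
              x$sample_id, d[1], d[2],
              if (is.null(x$vessel_mask)) "no" else "yes",
              if (is.null(x$av_labels)) "no" else "yes"))
  invisible(x)
}

#' Encode an A/V label map as an RGB array using the canonical colors
#' @param av H x W matrix of label codes
#' @return H x W x 3 array, 0..255
#' @export
av_to_rgb <- function(av) {
  d <- dim(av)
  out <- array(0, dim = c(d[1], d[2], 3L))
  for (code in 1:3) {
    cc <- .av_colors[code + 1L, ]
    hit <- av == code
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[hit] <- cc[ch]
      out[, , ch] <- pl
    }
  }
  out
}

#' Write prediction artifacts for one sample
#'
#' Writes three PNGs into `out_dir`: the vessel probability map as 8-bit
#' grayscale (`round(p * 255)`), the A/V classes color-coded with the
#' canonical palette, and the binary vessel mask thresholded at 0.5.
#'
#' @param sample_id identifier used as the filename stem
#' @param vessel_prob H x W matrix of vessel probabilities in [0,1]
#' @param av_classes H x W matrix of label codes
#' @param out_dir output directory (created if missing)
#' @return named character vector of the three file paths
#' @export
write_prediction <- function(sample_id, vessel_prob, av_classes, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    vessel_prob = file.path(out_dir, paste0(sample_id, "_vessel_prob.png")),
    av = file.path(out_dir, paste0(sample_id, "_av.png")),
    vessel_mask = file.path(out_dir, paste0(sample_id, "_vessel_mask.png"))
  )
  png::writePNG(round(vessel_prob * 255) / 255, paths[["vessel_prob"]])
  write_image(av_to_rgb(av_classes), paths[["av"]])
  png::writePNG((vessel_prob >= 0.5) * 1, paths[["vessel_mask"]])
  paths
}
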