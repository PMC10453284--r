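# Seeded synthetic fundus-like samples: branching vascular trees drawn as
# hard (non-anti-aliased) thick polylines on a textured mid-gray background
# inside a circular field of view.  Half of the trees are arteries, half
# veins; arteries are rendered brighter and more orange.  Pixels where an
# artery and a vein overlap are labeled uncertain, mirroring the crossing
# ambiguity of DRIVE-style annotations.  Ground truth is exact by
# construction, which matters more than photorealism for testing.

#' Configuration for the synthetic fundus generator
#'
#' @param height,width image size in pixels (>= 64)
#' @param n_trees number of vascular trees; alternating artery/vein
#' @param branch_depth binary branching levels per tree
#' @param root_caliber stroke width of the root segment, pixels
#' @param taper per-level caliber ratio in (0,1); calibers strictly decrease
#' @param artery_color_mean,vein_color_mean RGB triples (0..255); defaults
#'   make arteries brighter/more orange than veins, as in real fundus images
#' @param color_noise_sd per-pixel Gaussian color noise, intensity units
#' @param background_texture_sd Gaussian texture of the mid-gray background
#' @param seed integer; identical configs give bit-identical samples
#' @return a `synth_config` list
#' @export
synth_config <- function(height = 256, width = 256, n_trees = 4,
                         branch_depth = 4, root_caliber = 6, taper = 0.75,
                         artery_color_mean = c(205, 110, 70),
                         vein_color_mean = c(110, 45, 55),
                         color_noise_sd = 8, background_texture_sd = 8,
                         seed = 1L) {
  cfg <- list(height = height, width = width, n_trees = n_trees,
              branch_depth = branch_depth, root_caliber = root_caliber,
              taper = taper, artery_color_mean = artery_color_mean,
              vein_color_mean = vein_color_mean,
              color_noise_sd = color_noise_sd,
              background_texture_sd = background_texture_sd,
              seed = as.integer(seed))
  if (height < 64 || width < 64) stop("synthetic images must be at least 64x64")
  if (n_trees < 1) stop("degenerate config: n_trees must be >= 1")
  if (root_caliber < 1) stop("degenerate config: root_caliber must be >= 1")
  if (taper <= 0 || taper >= 1) stop("taper must lie strictly inside (0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

#' Evaluate an expression under a private RNG stream
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state, so
#' seeded helpers never perturb the surrounding random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stamp a thick line segment into a logical mask (TRUE = stroke), restricted
# to `fov`.  Walks the segment at sub-pixel steps and stamps a disc of
# radius caliber/2 at each step; no anti-aliasing, so the mask is exact.
stamp_segment <- function(mask, fov, p0, p1, caliber) {
  h <- nrow(mask); w <- ncol(mask)
  r <- max(caliber / 2, 0.5)
  ri <- ceiling(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  len <- sqrt(sum((p1 - p0)^2))
  nstep <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = nstep)
  cr <- round(p0[1] + t * (p1[1] - p0[1]))
  cc <- round(p0[2] + t * (p1[2] - p0[2]))
  keep <- !duplicated(cbind(cr, cc))
  cr <- cr[keep]; cc <- cc[keep]
  rows <- outer(off$dr, cr, `+`)
  cols <- outer(off$dc, cc, `+`)
  ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  idx <- cbind(rows[ok], cols[ok])
  idx <- idx[fov[idx], , drop = FALSE]
  mask[idx] <- TRUE
  mask
}

# Draw one binary-branching tree; returns a logical stroke mask.
draw_tree <- function(h, w, fov, root, dir0, depth, root_caliber, taper) {
  mask <- matrix(FALSE, h, w)
  seg_len <- 0.22 * min(h, w)
  grow <- function(p, ang, level) {
    if (level > depth) return(invisible(NULL))
    len <- seg_len * 0.85^level
    q <- p + len * c(sin(ang), cos(ang))
    cal <- root_caliber * taper^level
    mask <<- stamp_segment(mask, fov, p, q, cal)
    if (level < depth) {
      spread <- stats::runif(1, 0.25, 0.6)
      wob <- stats::rnorm(2, sd = 0.12)
      grow(q, ang - spread + wob[1], level + 1)
      grow(q, ang + spread + wob[2], level + 1)
    }
    invisible(NULL)
  }
  grow(root, dir0, 0)
  mask
}

#' Generate one synthetic fundus sample
#'
#' The vessel mask is exactly the union of all drawn strokes; A/V labels mark
#' each stroke with its tree's class and artery-vein overlaps as uncertain.
#' With `n_trees >= 2` at least one artery-vein crossing is forced.
#'
#' @param cfg a [synth_config()]
#' @return a [fundus_sample()] with image, vessel mask and A/V labels
#' @export
generate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    ctr <- c(h, w) / 2
    rad <- 0.48 * min(h, w)
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    fov <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2

    art <- matrix(FALSE, h, w)
    ven <- matrix(FALSE, h, w)
    for (i in seq_len(cfg$n_trees)) {
      is_artery <- i %% 2 == 1
      ang0 <- stats::runif(1, 0, 2 * pi)
      root <- ctr + 0.85 * rad * c(sin(ang0), cos(ang0))
      dir0 <- ang0 + pi + stats::rnorm(1, sd = 0.3)  # roughly toward center
      tm <- draw_tree(h, w, fov, root, dir0, cfg$branch_depth,
                      cfg$root_caliber, cfg$taper)
      if (is_artery) art <- art | tm else ven <- ven | tm
    }
    if (cfg$n_trees >= 2 && !any(art & ven)) {
      # force one artery-vein crossing through the center
      cal <- max(2, cfg$root_caliber * cfg$taper)
      art <- stamp_segment(art, fov, ctr - c(0.3 * rad, 0.3 * rad),
                           ctr + c(0.3 * rad, 0.3 * rad), cal)
      ven <- stamp_segment(ven, fov, ctr - c(-0.3 * rad, 0.3 * rad),
                           ctr + c(-0.3 * rad, 0.3 * rad), cal)
    }

    av <- matrix(AV_BACKGROUND, h, w)
    av[art] <- AV_ARTERY
    av[ven] <- AV_VEIN
    av[art & ven] <- AV_UNCERTAIN
    vessel <- (art | ven) * 1L
    storage.mode(av) <- "integer"

    img <- array(0, dim = c(h, w, 3))
    npix <- h * w
    for (ch in 1:3) {
      pl <- matrix(128 + stats::rnorm(npix, sd = cfg$background_texture_sd), h, w)
      a_only <- art & !ven
      v_only <- ven & !art
      both <- art & ven
      pl[a_only] <- cfg$artery_color_mean[ch] +
        stats::rnorm(sum(a_only), sd = cfg$color_noise_sd)
      pl[v_only] <- cfg$vein_color_mean[ch] +
        stats::rnorm(sum(v_only), sd = cfg$color_noise_sd)
      pl[both] <- (cfg$artery_color_mean[ch] + cfg$vein_color_mean[ch]) / 2 +
        stats::rnorm(sum(both), sd = cfg$color_noise_sd)
      pl[!fov] <- 0
      img[, , ch] <- pl
    }
    img <- round(pmin(pmax(img, 0), 255))

    fundus_sample(img, vessel, av, sample_id = sprintf("synth_%08d", cfg$seed))
  })
}

#' Generate and write a synthetic dataset with a manifest
#'
#' Per-sample seeds are derived deterministically from `cfg$seed`, so two
#' runs with the same config produce byte-identical files.
#'
#' @param cfg a [synth_config()]; per-sample seeds override `cfg$seed`
#' @param n_samples number of samples (>= 1)
#' @param out_dir output directory
#' @return the manifest: list of entries with `sample_id`, `image`, `mask`,
#'   `av` paths (also written to `manifest.json`)
#' @export
generate_dataset <- function(cfg, n_samples, out_dir) {
  stopifnot(n_samples >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    ci <- cfg
    ci$seed <- as.integer((cfg$seed + i * 9973L) %% .Machine$integer.max)
    s <- generate_sample(ci)
    id <- sprintf("synth_%03d", i)
    paths <- list(
      sample_id = id,
      image = file.path(out_dir, paste0(id, ".png")),
      mask = file.path(out_dir, paste0(id, "_mask.png")),
      av = file.path(out_dir, paste0(id, "_av.png"))
    )
    write_image(s$image, paths$image)
    png::writePNG(s$vessel_mask * 1, paths$mask)
    write_image(av_to_rgb(s$av_labels), paths$av)
    manifest[[i]] <- paths
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read the samples listed in a dataset manifest
#' @param manifest a manifest list or a path to `manifest.json`
#' @return list of [fundus_sample()]s
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  lapply(manifest, function(e) {
    read_sample(e$image, e$mask, e$av, sample_id = e$sample_id)
  })
}
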