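# ---------------------------------------------------------------------------
# Deterministic geometric and sampling operators on registered CT volumes:
# midsagittal mirroring, mirror subtraction, hemisphere splitting, axial MIP,
# slice-bag extraction and the offline augmentation suite.
# ---------------------------------------------------------------------------

TEMPLATE_SHAPES <- list(
  "mni-2mm" = c(91L, 109L, 91L),
  "mni-1mm" = c(182L, 218L, 182L)
)

#' Construct a CT volume
#'
#' A `Volume3D` stores a single-channel CT volume as a 3D array with the fixed
#' axis convention (LR, PA, IS): axis 1 runs left to right, axis 2 posterior
#' to anterior, axis 3 inferior to superior, matching MNI RAS axis ordering.
#' The midsagittal plane (MSP) is perpendicular to axis 1 at its centre.
#'
#' @param voxels 3D numeric array of intensities (Hounsfield-unit-like).
#' @param template One of `"mni-2mm"` (enforced shape 91 x 109 x 91, the NCCT
#'   grid), `"mni-1mm"` (182 x 218 x 182, the CTA grid) or `"free"`.
#' @param spacing Voxel spacing in mm per axis; defaults to the template
#'   spacing (2 or 1 mm) or 1 mm for free grids.
#' @return An object of class `strokesight_volume`.
#' @export
volume3d <- function(voxels, template = c("free", "mni-2mm", "mni-1mm"),
                     spacing = NULL) {
  template <- match.arg(template)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array ordered (LR, PA, IS)")
  if (!all(is.finite(voxels)))
    stop("voxels must all be finite")
  if (template != "free") {
    want <- TEMPLATE_SHAPES[[template]]
    if (!identical(dim(voxels), want))
      stop(sprintf("template %s requires shape %s, got %s", template,
                   paste(want, collapse = "x"),
                   paste(dim(voxels), collapse = "x")))
    if (is.null(spacing))
      spacing <- rep(if (template == "mni-2mm") 2 else 1, 3)
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  structure(list(voxels = voxels, shape = dim(voxels), template = template,
                 spacing = as.numeric(spacing)),
            class = "strokesight_volume")
}

#' @export
print.strokesight_volume <- function(x, ...) {
  cat(sprintf("<Volume3D %s, template %s, spacing %s mm, range [%.1f, %.1f]>\n",
              paste(x$shape, collapse = "x"), x$template,
              paste(x$spacing, collapse = "/"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a 2D image
#'
#' Axial-plane images (MIPs, extracted slices) are stored with rows along the
#' posterior-anterior axis and columns along the left-right axis, so a MIP of
#' an MNI 1 mm CTA grid has shape 218 x 182.
#'
#' @param pixels Numeric matrix.
#' @return Object of class `strokesight_image`.
#' @export
image2d <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!all(is.finite(pixels))) stop("pixels must all be finite")
  structure(list(pixels = pixels, shape = dim(pixels)),
            class = "strokesight_image")
}

assert_volume <- function(vol) {
  if (!inherits(vol, "strokesight_volume"))
    stop("expected a Volume3D built with volume3d(); ",
         "raw arrays carry no axis-order metadata")
  invisible(vol)
}

#' Mirror a volume across the midsagittal plane
#'
#' Reverses the left-right axis. An involution and an intensity isometry:
#' applying it twice returns the input exactly and the voxel multiset is
#' unchanged.
#'
#' @param vol A [volume3d()] object.
#' @return The mirrored volume (same shape, template and spacing).
#' @export
mirror_msp <- function(vol) {
  assert_volume(vol)
  v <- vol$voxels[vol$shape[1]:1, , , drop = FALSE]
  volume3d(v, template = vol$template, spacing = vol$spacing)
}

#' Subtract the mirrored volume
#'
#' Computes `vol - mirror_msp(vol)`, highlighting interhemispheric asymmetry
#' (the "baseline mirror" model input). The result is exactly anti-symmetric:
#' mirroring the output flips its sign.
#'
#' @inheritParams mirror_msp
#' @return A volume of differences with the same shape (template `"free"`,
#'   since values are no longer HU-like).
#' @export
mirror_subtract <- function(vol) {
  assert_volume(vol)
  v <- vol$voxels - vol$voxels[vol$shape[1]:1, , , drop = FALSE]
  volume3d(v, template = "free", spacing = vol$spacing)
}

#' Split a volume into aligned hemispheres
#'
#' Cuts the volume at the midsagittal plane. For an odd left-right extent the
#' central sagittal plane belongs to neither hemisphere and is dropped (so
#' both halves have equal shape, as weight-shared Siamese encoders require).
#' The right half is mirrored so homologous voxels share indices: position
#' `i` of either half lies at the same distance from the midline.
#'
#' @inheritParams mirror_msp
#' @return A list with `left` and `right` (both `Volume3D`, template
#'   `"free"`) and `midline_policy` (`"dropped-central-plane"` or `"none"`).
#' @export
split_hemispheres <- function(vol) {
  assert_volume(vol)
  n <- vol$shape[1]
  if (n < 3L) stop("left-right extent must be at least 3 to split")
  h <- (n - (n %% 2L)) %/% 2L
  if (n %% 2L == 1L) h <- (n - 1L) %/% 2L
  left <- vol$voxels[seq_len(h), , , drop = FALSE]
  right <- vol$voxels[n:(n - h + 1L), , , drop = FALSE]
  list(left = volume3d(left, spacing = vol$spacing),
       right = volume3d(right, spacing = vol$spacing),
       midline_policy = if (n %% 2L == 1L) "dropped-central-plane" else "none")
}

#' Axial maximum intensity projection
#'
#' Collapses an inclusive slab of axial slices to a single 2D image by taking
#' the per-pixel maximum along the inferior-superior axis — the standard way
#' of making CTA vessel trees (and their occlusion-induced asymmetries)
#' visible in one image. Slice indices are 0-based and inclusive; the default
#' slab 45..100 covers the middle-cerebral-artery territory on the MNI 1 mm
#' grid.
#'
#' @inheritParams mirror_msp
#' @param z_lo,z_hi 0-based inclusive slice range. Defaults 45 and 100 are
#'   applied for `mni-1mm` volumes; other templates require explicit values.
#' @return An [image2d()] of shape (PA extent, LR extent) — 218 x 182 for the
#'   MNI 1 mm grid.
#' @export
mip_axial <- function(vol, z_lo = NULL, z_hi = NULL) {
  assert_volume(vol)
  if (is.null(z_lo) || is.null(z_hi)) {
    if (vol$template == "mni-1mm") {
      if (is.null(z_lo)) z_lo <- 45L
      if (is.null(z_hi)) z_hi <- 100L
    } else {
      stop("z_lo and z_hi must be given for non mni-1mm volumes")
    }
  }
  z_lo <- as.integer(z_lo); z_hi <- as.integer(z_hi)
  if (z_lo < 0L || z_hi < z_lo || z_hi >= vol$shape[3])
    stop("slice range outside volume: need 0 <= z_lo <= z_hi < IS extent")
  m <- cpp_mip_axial(vol$voxels, vol$shape, z_lo, z_hi)
  image2d(t(m))  # (PA, LR)
}

#' Extract the axial slice bag for multiple-instance learning
#'
#' Slices with fewer than `min_fg_pixels` pixels strictly above
#' `fg_hu_threshold` are removed (mostly-background slices carry no brain);
#' a slice with exactly `min_fg_pixels` suprathreshold pixels is kept.
#' Surviving slices are returned inferior to superior.
#'
#' @inheritParams mirror_msp
#' @param min_fg_pixels Minimum number of foreground pixels (default 100).
#' @param fg_hu_threshold Foreground intensity threshold (default 0 HU).
#' @return A `strokesight_slicebag`: list of [image2d()] `instances`, the
#'   1-based `kept_indices` of surviving slices on the original grid, and the
#'   filter settings.
#' @export
extract_slice_bag <- function(vol, min_fg_pixels = 100L, fg_hu_threshold = 0) {
  assert_volume(vol)
  counts <- apply(vol$voxels > fg_hu_threshold, 3, sum)
  keep <- which(counts >= min_fg_pixels)
  if (length(keep) == 0L)
    stop("empty slice bag: every axial slice fell below the foreground filter")
  instances <- lapply(keep, function(z) image2d(t(vol$voxels[, , z])))
  structure(list(instances = instances, kept_indices = keep,
                 min_fg_pixels = as.integer(min_fg_pixels),
                 fg_hu_threshold = fg_hu_threshold),
            class = "strokesight_slicebag")
}

#' Augmentation specification
#'
#' Describes one stochastic transform draw for offline training-set
#' augmentation: midsagittal mirror, random rotation of at most
#' `max_rotation_deg` degrees about each axis, random elastic deformation on
#' a cubic control grid (`elastic_control_points` per axis, maximum control
#' displacement `elastic_max_displacement` mm, linear interpolation) and
#' additive Gaussian noise with mean `noise_mean` and standard deviation
#' `noise_std`. The seed fully determines the sampled transform.
#'
#' @param mirror,rotate,elastic,noise Logical flags enabling each transform;
#'   enabled transforms are composed in that order.
#' @param max_rotation_deg Maximum rotation per axis, degrees (default 10).
#' @param elastic_control_points Control points per axis (default 7).
#' @param elastic_max_displacement Maximum control-point displacement in mm
#'   (default 7.5).
#' @param noise_mean,noise_std Gaussian noise parameters (defaults 5 and 2).
#' @param seed Integer seed.
#' @return An `strokesight_augspec` list.
#' @export
augmentation_spec <- function(mirror = FALSE, rotate = FALSE, elastic = FALSE,
                              noise = FALSE, max_rotation_deg = 10,
                              elastic_control_points = 7L,
                              elastic_max_displacement = 7.5,
                              noise_mean = 5, noise_std = 2, seed = 1L) {
  if (max_rotation_deg < 0 || elastic_max_displacement < 0 || noise_std < 0 ||
      elastic_control_points < 2L)
    stop("augmentation magnitudes must be non-negative (and >= 2 control points)")
  structure(list(mirror = mirror, rotate = rotate, elastic = elastic,
                 noise = noise, max_rotation_deg = max_rotation_deg,
                 elastic_control_points = as.integer(elastic_control_points),
                 elastic_max_displacement = elastic_max_displacement,
                 noise_mean = noise_mean, noise_std = noise_std,
                 seed = as.integer(seed)),
            class = "strokesight_augspec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

identity_maps <- function(d) {
  ix <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  list(x = ix, y = iy, z = iz)
}

# Trilinear resize of a 3D array to new dims (used to upsample the elastic
# control grid to the image grid).
trilinear_resize <- function(a, newdim) {
  d <- dim(a)
  sc <- ifelse(newdim > 1, (d - 1) / (newdim - 1), 0)
  maps <- identity_maps(newdim)
  out <- cpp_warp3d(a, d, maps$x * sc[1], maps$y * sc[2], maps$z * sc[3], 0)
  array(out, newdim)
}

#' Apply a seeded augmentation to a volume
#'
#' Applies the transforms enabled in `spec`, composed mirror, rotation,
#' elastic, noise. The output has identical shape; with a fixed seed the
#' output is bit-reproducible (a pure function of volume and spec). Voxels
#' resampled from outside the volume are filled with 0 (air-subtracted
#' background on registered CT).
#'
#' @inheritParams mirror_msp
#' @param spec An [augmentation_spec()].
#' @return The transformed volume.
#' @export
augment <- function(vol, spec) {
  assert_volume(vol)
  if (!inherits(spec, "strokesight_augspec")) stop("spec must be an augmentation_spec()")
  with_seed(spec$seed, {
    v <- vol$voxels
    d <- dim(v)
    if (spec$mirror) v <- v[d[1]:1, , , drop = FALSE]
    if (spec$rotate) {
      ang <- stats::runif(3, -spec$max_rotation_deg, spec$max_rotation_deg) * pi / 180
      cx <- cos(ang[1]); sx <- sin(ang[1])
      cy <- cos(ang[2]); sy <- sin(ang[2])
      cz <- cos(ang[3]); sz <- sin(ang[3])
      Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
      Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
      Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
      Rinv <- t(Rz %*% Ry %*% Rx)  # inverse map: rotate target coords back
      ctr <- (d - 1) / 2
      maps <- identity_maps(d)
      px <- maps$x - ctr[1]; py <- maps$y - ctr[2]; pz <- maps$z - ctr[3]
      mx <- Rinv[1, 1] * px + Rinv[1, 2] * py + Rinv[1, 3] * pz + ctr[1]
      my <- Rinv[2, 1] * px + Rinv[2, 2] * py + Rinv[2, 3] * pz + ctr[2]
      mz <- Rinv[3, 1] * px + Rinv[3, 2] * py + Rinv[3, 3] * pz + ctr[3]
      v <- array(cpp_warp3d(v, d, mx, my, mz, 0), d)
    }
    if (spec$elastic) {
      ncp <- spec$elastic_control_points
      disp <- lapply(1:3, function(ax) {
        coarse <- array(stats::runif(ncp^3, -spec$elastic_max_displacement,
                                     spec$elastic_max_displacement) / vol$spacing[ax],
                        rep(ncp, 3))
        trilinear_resize(coarse, d)
      })
      maps <- identity_maps(d)
      v <- array(cpp_warp3d(v, d, maps$x + as.numeric(disp[[1]]),
                            maps$y + as.numeric(disp[[2]]),
                            maps$z + as.numeric(disp[[3]]), 0), d)
    }
    if (spec$noise)
      v <- v + stats::rnorm(length(v), spec$noise_mean, spec$noise_std)
    volume3d(v, template = vol$template, spacing = vol$spacing)
  })
}

#' Offline fourfold augmentation of a training set
#'
#' Expands a list of volumes to four times its size: each original volume is
#' kept and three augmented copies are added, each copy drawing one transform
#' uniformly from `transforms` with a seed derived from `seed`, the volume
#' index and the copy index. Returns the expanded list plus a provenance
#' manifest (one row per output volume) suitable for writing as delimited
#' text.
#'
#' @param vols List of [volume3d()] objects.
#' @param labels Optional label vector, replicated alongside.
#' @param copies Augmented copies per volume (default 3, i.e. 4x total).
#' @param transforms Candidate transforms.
#' @param seed Integer seed.
#' @return List with `volumes`, `labels` (if given) and `manifest`.
#' @export
augment_fourfold <- function(vols, labels = NULL, copies = 3L,
                             transforms = c("mirror", "rotate", "elastic", "noise"),
                             seed = 1L) {
  out <- list()
  lab <- c()
  man <- list()
  for (i in seq_along(vols)) {
    out[[length(out) + 1L]] <- vols[[i]]
    man[[length(man) + 1L]] <- data.frame(source = i, copy = 0L,
                                          transform = "none", seed = NA_integer_)
    if (!is.null(labels)) lab <- c(lab, labels[i])
    for (j in seq_len(copies)) {
      s <- (seed * 10007L + i * 131L + j) %% .Machine$integer.max
      tr <- with_seed(s, sample(transforms, 1L))
      spec <- augmentation_spec(mirror = tr == "mirror", rotate = tr == "rotate",
                                elastic = tr == "elastic", noise = tr == "noise",
                                seed = s + 1L)
      out[[length(out) + 1L]] <- augment(vols[[i]], spec)
      man[[length(man) + 1L]] <- data.frame(source = i, copy = j,
                                            transform = tr, seed = s + 1L)
      if (!is.null(labels)) lab <- c(lab, labels[i])
    }
  }
  res <- list(volumes = out, manifest = do.call(rbind, man))
  if (!is.null(labels)) res$labels <- lab
  res
}

#' Downscale a volume by integer block averaging
#'
#' Reduces each axis by `factor` using block means (edge blocks average the
#' voxels available), giving output extents `ceiling(dim / factor)`. Used to
#' run the 3D models at reduced resolution.
#'
#' @inheritParams mirror_msp
#' @param factor Integer downscale factor per axis.
#' @return A `Volume3D` on a `"free"` grid with spacing scaled by `factor`.
#' @export
downscale_volume <- function(vol, factor = 2L) {
  assert_volume(vol)
  v <- vol$voxels
  for (ax in 1:3) {
    d <- dim(v)
    g <- (seq_len(d[1]) - 1L) %/% factor
    m <- matrix(v, d[1], d[2] * d[3])
    s <- rowsum(m, g)
    cnt <- as.numeric(table(g))
    v <- array(s / cnt, c(nrow(s), d[2], d[3]))
    v <- aperm(v, c(2, 3, 1))
  }
  volume3d(v, spacing = vol$spacing * factor)
}

# --- NIfTI I/O ---------------------------------------------------------------

#' Read a registered CT volume from NIfTI
#'
#' Loads a `.nii`/`.nii.gz` file, reorients the voxel grid to RAS so the array
#' axes are (LR, PA, IS), and tags the volume with the matching MNI template
#' when the shape is recognised.
#'
#' @param path Path to a NIfTI file.
#' @return A [volume3d()] object.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (RNifti::orientation(img) != "RAS") RNifti::orientation(img) <- "RAS"
  v <- as.array(img)
  if (length(dim(v)) == 4L && dim(v)[4] == 1L) dim(v) <- dim(v)[1:3]
  v <- array(as.numeric(v), dim(v))  # drop NIfTI header attributes
  spacing <- abs(RNifti::pixdim(img)[1:3])
  template <- "free"
  for (tn in names(TEMPLATE_SHAPES))
    if (identical(dim(v), TEMPLATE_SHAPES[[tn]])) template <- tn
  volume3d(v, template = template, spacing = spacing)
}

#' Write a volume to NIfTI
#'
#' Writes with an RAS affine built from the voxel spacing, so a round trip
#' through [read_volume()] reproduces the array.
#'
#' @inheritParams mirror_msp
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
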