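# ---------------------------------------------------------------------------
# Synthetic fixtures: brain-like NCCT phantoms with planted unilateral
# hypodense lesions, CTA phantoms with symmetric vessel trees and unilateral
# attenuation (occlusions), and a cohort generator with realistic marginals
# and a known logistic outcome model. Geometric primitives only — the
# invariants the architectures exploit (midsagittal symmetry, planted
# asymmetry) are what matters, not anatomy.
# ---------------------------------------------------------------------------

#' Phantom generator specification
#'
#' @param grid `"mni-2mm"` (91x109x91 NCCT grid) or `"mni-1mm"`
#'   (182x218x182 CTA grid).
#' @param n_subjects Number of phantoms.
#' @param lesion_prob Probability a subject receives a unilateral lesion (and
#'   the poor-outcome / occlusion label).
#' @param lesion_intensity_delta Additive HU-like shift inside the lesion
#'   (negative = hypodense ischemic tissue; default -15).
#' @param lesion_radius_range Lesion radius range in voxels.
#' @param vessel_tree Add the bright CTA vessel tree (required for
#'   [gen_cta_phantoms()]).
#' @param base_noise_std Within-brain noise standard deviation. Noise is
#'   generated as a bilaterally mirrored field plus an independent component
#'   of a quarter of this sd, emulating registered anatomy shared across
#'   hemispheres with a small acquisition-noise residual; absent a lesion the
#'   voxelwise mirror asymmetry stays well below `3 * base_noise_std`.
#' @param seed Integer seed; regeneration is bit-identical.
#' @return A `strokesight_phantom_spec`.
#' @export
phantom_spec <- function(grid = c("mni-2mm", "mni-1mm"), n_subjects = 10L,
                         lesion_prob = 0.5, lesion_intensity_delta = -15,
                         lesion_radius_range = c(6L, 12L), vessel_tree = FALSE,
                         base_noise_std = 2, seed = 1L) {
  grid <- match.arg(grid)
  structure(list(grid = grid, n_subjects = as.integer(n_subjects),
                 lesion_prob = lesion_prob,
                 lesion_intensity_delta = lesion_intensity_delta,
                 lesion_radius_range = lesion_radius_range,
                 vessel_tree = vessel_tree, base_noise_std = base_noise_std,
                 seed = as.integer(seed)),
            class = "strokesight_phantom_spec")
}

# mirrored-plus-independent noise field inside a mask
symmetric_noise <- function(d, sd_total, mask) {
  half <- array(0, d)
  hx <- ceiling(d[1] / 2)
  base <- array(stats::rnorm(hx * d[2] * d[3], 0, sd_total), c(hx, d[2], d[3]))
  half[seq_len(hx), , ] <- base
  half[d[1]:(d[1] - hx + 1L), , ] <- base[seq_len(hx), , ]
  indep <- array(stats::rnorm(prod(d), 0, sd_total / 4), d)
  (half + indep) * mask
}

ellipsoid_mask <- function(d, semi_frac = c(0.42, 0.44, 0.42)) {
  ctr <- (d + 1) / 2
  ax <- semi_frac * d
  xs <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
  ys <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
  zs <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
  r2 <- outer(outer(xs, ys, "+"), zs, "+")
  list(mask = r2 <= 1, r2 = r2)
}

# sample a strictly unilateral lesion centre + radius inside the brain
sample_lesion <- function(d, mask, radius_range) {
  mid <- (d[1] + 1) / 2
  repeat {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    if (r >= mid - 2) stop("lesion radius exceeds hemisphere extent")
    side <- sample(c(-1, 1), 1)
    cx <- round(mid + side * stats::runif(1, r + 2, mid - r - 3))
    cy <- round(stats::runif(1, d[2] * 0.3, d[2] * 0.7))
    cz <- round(stats::runif(1, d[3] * 0.3, d[3] * 0.7))
    if (cx >= 1 && cx <= d[1] && mask[cx, cy, cz]) {
      return(list(cx = cx, cy = cy, cz = cz, r = r,
                  side = if (side < 0) "left" else "right"))
    }
  }
}

# voxel offsets of a sphere of the given radius around the origin
sphere_offsets <- function(radius) {
  rr <- ceiling(radius)
  g <- expand.grid(x = -rr:rr, y = -rr:rr, z = -rr:rr)
  g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
}

# flat indices of sphere voxels at integer centres, clipped to the grid
sphere_indices <- function(centres, radius, d) {
  off <- sphere_offsets(radius)
  k <- nrow(off)
  xs <- rep(centres[, 1], each = k) + off$x
  ys <- rep(centres[, 2], each = k) + off$y
  zs <- rep(centres[, 3], each = k) + off$z
  ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3]
  unique((zs[ok] - 1) * d[1] * d[2] + (ys[ok] - 1) * d[1] + xs[ok])
}

#' Materialise a lesion's ground-truth mask
#'
#' @param truth_row One row of the `truth` data frame returned by the
#'   phantom generators.
#' @param shape Volume shape.
#' @return Logical 3D array.
#' @export
lesion_mask <- function(truth_row, shape) {
  m <- array(FALSE, shape)
  if (is.na(truth_row$cx)) return(m)
  idx <- sphere_indices(cbind(truth_row$cx, truth_row$cy, truth_row$cz),
                        truth_row$r, shape)
  m[idx] <- TRUE
  m
}

#' Generate labelled NCCT phantoms
#'
#' Each phantom is an ellipsoidal "brain" (interior around 25-40 HU with a
#' smooth symmetric radial gradient) on a zero background, mirror-symmetric
#' up to noise. With probability `lesion_prob` a strictly unilateral
#' spherical hypodense lesion is planted and the subject is labelled
#' poor-outcome (1); lesion geometry is recorded as ground truth.
#'
#' @param spec A [phantom_spec()] with `grid = "mni-2mm"`.
#' @param downscale Optional integer factor applied to each phantom via
#'   [downscale_volume()] before returning (keeps memory bounded when
#'   training at reduced resolution); ground-truth geometry stays in
#'   original-grid coordinates.
#' @return List with `volumes` (list of [volume3d()]), `labels` (0/1) and
#'   `truth` (per-subject lesion geometry data frame).
#' @export
gen_ncct_phantoms <- function(spec, downscale = 1L) {
  stopifnot(inherits(spec, "strokesight_phantom_spec"), spec$grid == "mni-2mm")
  d <- TEMPLATE_SHAPES[[spec$grid]]
  geom <- ellipsoid_mask(d)
  vols <- vector("list", spec$n_subjects)
  labels <- integer(spec$n_subjects)
  truth <- list()
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_subjects)) {
      base_i <- stats::runif(1, 25, 40)
      v <- (base_i * (1 - 0.15 * geom$r2)) * geom$mask
      v <- v + symmetric_noise(d, spec$base_noise_std, geom$mask)
      has_lesion <- stats::runif(1) < spec$lesion_prob
      if (has_lesion) {
        les <- sample_lesion(d, geom$mask, spec$lesion_radius_range)
        idx <- sphere_indices(cbind(les$cx, les$cy, les$cz), les$r, d)
        idx <- idx[geom$mask[idx]]
        v[idx] <- v[idx] + spec$lesion_intensity_delta
        truth[[i]] <- data.frame(subject = i, label = 1L, side = les$side,
                                 cx = les$cx, cy = les$cy, cz = les$cz,
                                 r = les$r)
      } else {
        truth[[i]] <- data.frame(subject = i, label = 0L, side = NA_character_,
                                 cx = NA_real_, cy = NA_real_, cz = NA_real_,
                                 r = NA_real_)
      }
      labels[i] <- as.integer(has_lesion)
      vol <- volume3d(v, template = spec$grid)
      if (downscale > 1L) vol <- downscale_volume(vol, downscale)
      vols[[i]] <- vol
    }
  })
  list(volumes = vols, labels = labels, truth = do.call(rbind, truth))
}

# a smooth random vessel path in the left hemisphere, z kept inside the MIP slab
vessel_path <- function(d, n_pts = 140L) {
  nk <- 5L
  tt <- seq(0, 1, length.out = nk)
  kx <- stats::runif(nk, d[1] * 0.12, d[1] * 0.42)
  ky <- stats::runif(nk, d[2] * 0.25, d[2] * 0.75)
  kz <- sort(stats::runif(nk, d[3] * 0.28, d[3] * 0.52))
  ts <- seq(0, 1, length.out = n_pts)
  cbind(stats::spline(tt, kx, xout = ts)$y,
        stats::spline(tt, ky, xout = ts)$y,
        stats::spline(tt, kz, xout = ts)$y)
}

stamp_path <- function(v, path, radius, value) {
  idx <- sphere_indices(round(path), radius, dim(v))
  v[idx] <- pmax(v[idx], value)
  v
}

#' Generate labelled CTA phantoms (or their MIPs)
#'
#' Adds bright (far above brain tissue) branching curvilinear vessels,
#' mirror-symmetric across the midsagittal plane and confined to the axial
#' MIP slab. Occlusion-positive subjects (probability `lesion_prob`) have the
#' distal part of one branch on one side attenuated, so their MIP shows a
#' visible hemisphere asymmetry.
#'
#' @param spec A [phantom_spec()] with `grid = "mni-1mm"` and
#'   `vessel_tree = TRUE`.
#' @param return_what `"mips"` (default — memory-friendly: each full volume
#'   is projected and discarded) or `"volumes"`.
#' @param n_branches Vessel branches per hemisphere.
#' @return List with `mips` (list of [image2d()], 218 x 182) or `volumes`,
#'   plus `labels` and `truth` (attenuated branch/side records).
#' @export
gen_cta_phantoms <- function(spec, return_what = c("mips", "volumes"),
                             n_branches = 3L) {
  stopifnot(inherits(spec, "strokesight_phantom_spec"), spec$grid == "mni-1mm",
            isTRUE(spec$vessel_tree))
  return_what <- match.arg(return_what)
  d <- TEMPLATE_SHAPES[[spec$grid]]
  geom <- ellipsoid_mask(d)
  out <- vector("list", spec$n_subjects)
  labels <- integer(spec$n_subjects)
  truth <- list()
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_subjects)) {
      v <- (35 * (1 - 0.1 * geom$r2)) * geom$mask
      v <- v + symmetric_noise(d, spec$base_noise_std, geom$mask)
      occluded <- stats::runif(1) < spec$lesion_prob
      # branch/side are drawn unconditionally so the RNG stream (and hence
      # vessel geometry) is identical across occluded and intact regenerations
      occ_branch <- sample.int(n_branches, 1)
      occ_side <- sample(c("left", "right"), 1)
      if (!occluded) { occ_branch <- NA_integer_; occ_side <- NA_character_ }
      for (b in seq_len(n_branches)) {
        path <- vessel_path(d)
        mirrored <- path
        mirrored[, 1] <- d[1] + 1 - path[, 1]
        radius <- stats::runif(1, 1.6, 2.2)
        bright <- stats::runif(1, 260, 320)
        att <- bright * 0.12
        cut <- floor(nrow(path) * stats::runif(1, 0.35, 0.55))
        for (side in c("left", "right")) {
          pp <- if (side == "left") path else mirrored
          if (occluded && b == occ_branch && side == occ_side) {
            v <- stamp_path(v, pp[seq_len(cut), , drop = FALSE], radius, bright)
            v <- stamp_path(v, pp[(cut + 1):nrow(pp), , drop = FALSE], radius, att)
          } else {
            v <- stamp_path(v, pp, radius, bright)
          }
        }
      }
      labels[i] <- as.integer(occluded)
      truth[[i]] <- data.frame(subject = i, label = labels[i],
                               side = occ_side, branch = occ_branch)
      vol <- volume3d(v, template = spec$grid)
      out[[i]] <- if (return_what == "mips") mip_axial(vol) else vol
    }
  })
  res <- list(labels = labels, truth = do.call(rbind, truth))
  if (return_what == "mips") res$mips <- out else res$volumes <- out
  res
}

#' Downscale a 2D image by block averaging
#'
#' @param img An [image2d()].
#' @param factor Integer factor per axis.
#' @return The reduced [image2d()].
#' @export
downscale_image <- function(img, factor = 2L) {
  p <- img$pixels
  for (ax in 1:2) {
    g <- (seq_len(nrow(p)) - 1L) %/% factor
    p <- rowsum(p, g) / as.numeric(table(g))
    p <- t(p)
  }
  image2d(p)
}

#' Cohort generator specification
#'
#' Default marginals target the admission statistics typical of an ischemic
#' stroke cohort: median age about 71 (IQR 57-80), median NIHSS about 7.5,
#' onset-to-admission delay median 2 h, 38% visual field defects, 8%
#' decreased consciousness, median glucose 120 mg/dL, median ASPECTS 10
#' (IQR 8-10), occlusion prevalence 50%, and 34% poor outcomes.
#'
#' @param n Number of patients.
#' @param outcome_coefficients Named logistic coefficients on standardised
#'   predictors; the truth record is returned for recovery tests.
#' @param intercept Logistic intercept; if `NULL` it is calibrated so the
#'   expected poor-outcome prevalence equals `target_prevalence`.
#' @param target_prevalence Poor-outcome (mRS > 2) prevalence target
#'   (default 0.34).
#' @param missing_rate Fraction of predictor cells set missing completely at
#'   random.
#' @param seed Integer seed.
#' @return A `strokesight_cohort_spec`.
#' @export
cohort_spec <- function(n = 1000L,
                        outcome_coefficients = c(age = 0.8, nihss = 1.0,
                                                 delay = 0.1,
                                                 visual_defect = 0.15,
                                                 loc = 0.2, glucose = 0.25,
                                                 aspects = -0.35,
                                                 occlusion = 0.4),
                        intercept = NULL, target_prevalence = 0.34,
                        missing_rate = 0, seed = 1L) {
  stopifnot(all(is.finite(outcome_coefficients)))
  structure(list(n = as.integer(n),
                 outcome_coefficients = outcome_coefficients,
                 intercept = intercept,
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "strokesight_cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws the eight predictors from the configured marginals, builds a
#' logistic linear predictor on standardised variables with the spec's
#' coefficients, calibrates the intercept to the target prevalence (unless
#' given), samples the dichotomised outcome, and materialises `mrs90` as an
#' ordinal consistent with it (poor outcome uniform over 3-6, good over
#' 0-2). Optional missingness is injected completely at random into the
#' predictors. The truth (coefficients, intercept, per-patient event
#' probabilities) is returned for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (data frame) and `truth`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "strokesight_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    aspects_probs <- c(0.52, 0.12, 0.12, 0.08, 0.05, 0.04, 0.03, 0.02, 0.01,
                       0.005, 0.005)
    cohort <- data.frame(
      age = pmin(pmax(round(stats::rnorm(n, 70, 16)), 18), 100),
      nihss = pmin(round(stats::rgamma(n, shape = 1.4, scale = 6.8)), 42),
      delay = pmin(pmax(round(stats::rlnorm(n, log(2), 1.1), 1), 0.1), 72),
      visual_defect = stats::rbinom(n, 1, 0.38),
      loc = stats::rbinom(n, 1, 0.08),
      glucose = pmin(pmax(round(stats::rlnorm(n, log(120), 0.32)), 40), 500),
      aspects = sample(10:0, n, replace = TRUE, prob = aspects_probs),
      occlusion = stats::rbinom(n, 1, 0.5)
    )
    vars <- names(spec$outcome_coefficients)
    X <- as.matrix(cohort[vars])
    st <- standardize_fit(X)
    Z <- standardize_apply(X, st)
    lp <- as.numeric(Z %*% spec$outcome_coefficients)
    b0 <- spec$intercept
    if (is.null(b0)) {
      b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) -
                             spec$target_prevalence,
                           interval = c(-20, 20))$root
    }
    pr <- stats::plogis(b0 + lp)
    poor <- stats::rbinom(n, 1, pr)
    cohort$mrs90 <- ifelse(poor == 1, sample(3:6, n, replace = TRUE),
                           sample(0:2, n, replace = TRUE))
    if (spec$missing_rate > 0) {
      for (v in vars) {
        miss <- stats::runif(n) < spec$missing_rate
        cohort[[v]][miss] <- NA
      }
    }
    list(cohort = cohort,
         truth = list(coefficients = spec$outcome_coefficients,
                      intercept = b0, probs = pr,
                      standardization = st))
  })
}

#' Write a phantom demo dataset to disk
#'
#' Materialises NCCT phantoms (with ground-truth lesion tables), CTA MIPs
#' and a cohort as NIfTI + delimited text under `dir` — the programmatic
#' fixture entry point also used by the command-line interface.
#'
#' @param dir Output directory.
#' @param n_ncct,n_cta,n_cohort Sizes of the three fixture sets.
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
write_demo_fixtures <- function(dir, n_ncct = 20L, n_cta = 10L,
                                n_cohort = 500L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nc <- gen_ncct_phantoms(phantom_spec("mni-2mm", n_subjects = n_ncct,
                                       seed = seed))
  for (i in seq_along(nc$volumes))
    write_volume(nc$volumes[[i]], file.path(dir, sprintf("ncct_%03d.nii.gz", i)))
  utils::write.table(cbind(nc$truth, file = sprintf("ncct_%03d.nii.gz",
                                                    seq_len(n_ncct))),
                     file.path(dir, "ncct_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ct <- gen_cta_phantoms(phantom_spec("mni-1mm", n_subjects = n_cta,
                                      vessel_tree = TRUE, seed = seed + 1L))
  for (i in seq_along(ct$mips))
    utils::write.table(ct$mips[[i]]$pixels,
                       file.path(dir, sprintf("cta_mip_%03d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(ct$truth, file.path(dir, "cta_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  co <- gen_cohort(cohort_spec(n = n_cohort, seed = seed + 2L))
  utils::write.table(co$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(variable = names(co$truth$coefficients),
                                coefficient = co$truth$coefficients,
                                intercept = co$truth$intercept),
                     file.path(dir, "cohort_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
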