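#' Specification for a synthetic sagittal spine phantom
#'
#' Describes a stack of vertebral bodies rendered as a mid-sagittal label
#' mask: rounded-rectangle bodies whose anterior/middle/posterior column
#' heights are independently controllable through a deformity plan. The
#' superior endplate profile is remapped per deformity (the inferior endplate
#' stays fixed, keeping the posterior height the reference), with flat
#' plateaus under the three measurement bands and smooth cosine ramps between
#' them, so the rendered column heights equal the plan up to pixel
#' quantisation.
#'
#' @param n_vertebrae Number of vertebral bodies (>= 1).
#' @param base_posterior_height_mm Posterior (reference) height per vertebra
#'   in mm; scalar or length-`n_vertebrae` vector.
#' @param body_width_mm Anterior-posterior body width in mm.
#' @param disc_gap_mm Intervertebral gap in mm.
#' @param pixel_spacing_mm (row, col) pixel spacing in mm.
#' @param deformity_plan `NULL` or a data frame with columns `vertebra`
#'   (1-based index, unique, in range), `class` (one of `"wedge"`,
#'   `"biconcave"`, `"crush"`) and `target_hlr` in \[0, 1). Wedge removes
#'   height anteriorly, biconcave centrally, crush uniformly across all three
#'   columns (the height-loss-ratio blind spot: the ratio stays near zero).
#' @param corner_rounding Corner-rounding radius as a fraction of body width,
#'   in \[0, 0.5); kept clear of the measurement bands at the default 0.08.
#' @param margin_mm Background margin around the spine.
#' @param seed Integer seed recorded with the spec (the raster itself is a
#'   deterministic function of the spec; the seed drives cohort sampling and
#'   the mock detector).
#' @return An object of class `phantom_spec`.
#' @seealso [generate_spine()], [cohort_spec()]
#' @export
phantom_spec <- function(n_vertebrae,
                         base_posterior_height_mm = 22,
                         body_width_mm = 35,
                         disc_gap_mm = 4,
                         pixel_spacing_mm = c(1, 1),
                         deformity_plan = NULL,
                         corner_rounding = 0.08,
                         margin_mm = 5,
                         seed = 1L) {
  stopifnot(n_vertebrae >= 1, n_vertebrae == round(n_vertebrae))
  hp <- rep_len(base_posterior_height_mm, n_vertebrae)
  stopifnot(all(hp > 0), body_width_mm > 0, disc_gap_mm > 0, margin_mm > 0,
            length(pixel_spacing_mm) == 2, all(pixel_spacing_mm > 0),
            corner_rounding >= 0, corner_rounding < 0.5)
  if (is.null(deformity_plan)) {
    deformity_plan <- data.frame(vertebra = integer(), class = character(),
                                 target_hlr = numeric())
  }
  stopifnot(all(c("vertebra", "class", "target_hlr") %in% names(deformity_plan)))
  if (nrow(deformity_plan) > 0) {
    stopifnot(all(deformity_plan$vertebra %in% seq_len(n_vertebrae)),
              !anyDuplicated(deformity_plan$vertebra),
              all(deformity_plan$class %in% c("wedge", "biconcave", "crush")),
              all(deformity_plan$target_hlr >= 0),
              all(deformity_plan$target_hlr < 1))
  }
  structure(list(
    n_vertebrae = as.integer(n_vertebrae),
    base_posterior_height_mm = hp,
    body_width_mm = body_width_mm,
    disc_gap_mm = disc_gap_mm,
    pixel_spacing_mm = pixel_spacing_mm,
    deformity_plan = deformity_plan,
    corner_rounding = corner_rounding,
    margin_mm = margin_mm,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Per-vertebra nominal column heights (mm) implied by the deformity plan.
plan_heights <- function(spec) {
  out <- data.frame(vertebra = seq_len(spec$n_vertebrae),
                    class = "none",
                    target_hlr = 0,
                    Ha = spec$base_posterior_height_mm,
                    Hm = spec$base_posterior_height_mm,
                    Hp = spec$base_posterior_height_mm)
  dp <- spec$deformity_plan
  for (i in seq_len(nrow(dp))) {
    k <- dp$vertebra[i]
    t <- dp$target_hlr[i]
    hp <- out$Hp[k]
    out$class[k] <- dp$class[i]
    out$target_hlr[k] <- t
    switch(dp$class[i],
      wedge = { out$Ha[k] <- (1 - t) * hp; out$Hm[k] <- (1 - t / 2) * hp },
      biconcave = { out$Hm[k] <- (1 - t) * hp },
      crush = {
        out$Ha[k] <- (1 - t) * hp
        out$Hm[k] <- (1 - t) * hp
        out$Hp[k] <- (1 - t) * hp
      })
  }
  out
}

#' Render a spine phantom to a label mask with ground truth
#'
#' Produces an integer label mask (background 0, vertebra k labelled k) and a
#' per-vertebra truth table recording the rendered column heights, the true
#' height loss ratio, the fracture label (any planned deformity), the
#' deformity class, and the 0-based pixel bounding box. Truth heights are the
#' heights actually rasterised (the plan quantised to whole pixels), so
#' downstream morphometry can be judged against exactly what is in the image.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `vcf_phantom` with elements `mask` (integer matrix),
#'   `truth` (data frame) and `spec`.
#' @examples
#' ph <- generate_spine(phantom_spec(3, seed = 7))
#' ph$truth[, c("vertebra", "Ha_mm", "Hp_mm", "hlr", "fractured")]
#' @export
generate_spine <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rs <- spec$pixel_spacing_mm[1]
  cs <- spec$pixel_spacing_mm[2]
  plan <- plan_heights(spec)
  w_px <- round(spec$body_width_mm / cs)
  if (w_px < 10) stop("body width under 10 px at this spacing; enlarge or refine")
  gap_px <- max(1L, round(spec$disc_gap_mm / rs))
  margin_px <- max(1L, round(spec$margin_mm / min(rs, cs)))

  heights_px <- round(plan[, c("Ha", "Hm", "Hp")] / rs)
  too_small <- which(apply(heights_px, 1, min) < 3)
  if (length(too_small) > 0) {
    stop(sprintf("vertebra %d: column height under 3 px at this spacing",
                 too_small[1]))
  }

  n_rows <- 2L * margin_px + sum(heights_px$Hp) + gap_px * (spec$n_vertebrae - 1L)
  n_cols <- 2L * margin_px + w_px
  mask <- matrix(0L, n_rows, n_cols)

  truth <- plan
  truth$Ha_mm <- heights_px$Ha * rs
  truth$Hm_mm <- heights_px$Hm * rs
  truth$Hp_mm <- heights_px$Hp * rs
  truth$hlr <- compute_hlr(truth$Ha_mm, truth$Hm_mm, truth$Hp_mm)
  truth$fractured <- truth$class != "none"
  truth$x0 <- truth$y0 <- truth$x1 <- truth$y1 <- NA_integer_

  top <- margin_px + 1L
  for (k in seq_len(spec$n_vertebrae)) {
    hp <- heights_px$Hp[k]
    bottom <- top + hp - 1L
    prof <- endplate_profile(w_px, heights_px$Ha[k], heights_px$Hm[k], hp,
                             spec$corner_rounding)
    filled <- which(prof$top >= prof$bot)
    for (x in filled) {
      rows <- (bottom - prof$top[x] + 1L):(bottom - prof$bot[x] + 1L)
      mask[rows, margin_px + x] <- k
    }
    truth$x0[k] <- margin_px + min(filled) - 1L
    truth$x1[k] <- margin_px + max(filled) - 1L
    truth$y0[k] <- bottom - max(prof$top[filled])
    truth$y1[k] <- bottom - min(prof$bot[filled])
    top <- bottom + gap_px + 1L
  }
  truth <- truth[, c("vertebra", "class", "target_hlr", "Ha_mm", "Hm_mm",
                     "Hp_mm", "hlr", "fractured", "x0", "y0", "x1", "y1")]
  structure(list(mask = mask, truth = truth, spec = spec),
            class = "vcf_phantom")
}

# Column-height profile (in px, measured up from the fixed inferior endplate).
# Flat plateaus under the anterior/middle/posterior measurement bands
# ([0.10, 0.20], [0.45, 0.55], [0.80, 0.90] of the AP extent), cosine ramps
# between, quarter-circle corner rounding confined to the outer `rounding`
# fraction. Returns top/bot heights per column, 1-based from the bottom row.
endplate_profile <- function(w_px, ha, hm, hp, rounding) {
  frac <- (seq_len(w_px) - 0.5) / w_px
  plateau <- c(a1 = 0.25, m0 = 0.43, m1 = 0.57, p0 = 0.75)
  ramp <- function(f, f0, f1, h0, h1) {
    s <- (f - f0) / (f1 - f0)
    h0 + (h1 - h0) * (1 - cos(pi * s)) / 2
  }
  h <- ifelse(frac <= plateau["a1"], ha,
       ifelse(frac <= plateau["m0"], ramp(frac, plateau["a1"], plateau["m0"], ha, hm),
       ifelse(frac <= plateau["m1"], hm,
       ifelse(frac <= plateau["p0"], ramp(frac, plateau["m1"], plateau["p0"], hm, hp),
              hp))))
  h <- round(h)
  top <- h      # highest filled row, counted from the bottom of the slot
  bot <- rep(1L, w_px)
  r <- round(rounding * w_px)
  if (r >= 1) {
    dx <- pmin(frac, 1 - frac) * w_px    # px distance to the nearer AP end
    shave <- ifelse(dx < r, r - sqrt(pmax(0, r^2 - (r - dx)^2)), 0)
    shave <- pmin(round(shave), pmax(h %/% 3, 0))
    top <- top - shave
    bot <- bot + shave
  }
  list(top = pmax(top, 0L), bot = bot)
}

#' @export
print.vcf_phantom <- function(x, ...) {
  cat(sprintf("spine phantom: %d vertebrae (%d fractured), %d x %d raster, spacing %g x %g mm\n",
              nrow(x$truth), sum(x$truth$fractured), nrow(x$mask), ncol(x$mask),
              x$spec$pixel_spacing_mm[1], x$spec$pixel_spacing_mm[2]))
  invisible(x)
}

#' Stack a phantom slice into a thin 3D volume
#'
#' @param phantom A `vcf_phantom`.
#' @param n_slices Number of identical sagittal slices.
#' @return Integer 3D array (rows, cols, slices).
#' @export
phantom_volume <- function(phantom, n_slices = 5L) {
  stopifnot(inherits(phantom, "vcf_phantom"), n_slices >= 1)
  array(phantom$mask, dim = c(dim(phantom$mask), n_slices))
}

#' Simple intensity rendering of a phantom mask
#'
#' Assigns a constant bone attenuation to foreground and a soft-tissue value
#' to background, as a substrate for [apply_low_density_texture()].
#'
#' @param mask Label or binary matrix.
#' @param bone_hu,background_hu Intensity values.
#' @return Numeric matrix.
#' @export
phantom_intensity <- function(mask, bone_hu = 400, background_hu = -50) {
  out <- matrix(background_hu, nrow(mask), ncol(mask))
  out[mask > 0] <- bone_hu
  out
}

#' Simulate low bone density inside the trabecular compartment
#'
#' Randomly decreases the intensity of the mask's eroded interior (the
#' trabecular proxy) by per-voxel draws from `reduction_range`, leaving the
#' cortical rim (the contour-band zone) untouched. Seeded for
#' reproducibility.
#'
#' @param image Numeric matrix of intensities.
#' @param mask Binary or label matrix aligned with `image`.
#' @param reduction_range Length-2 non-negative range of the per-voxel
#'   intensity reduction.
#' @param seed Integer seed.
#' @param erode_radius_px Erosion radius defining the interior; default 2.
#' @return The modified image. If the interior is empty after erosion the
#'   image is returned unchanged with a warning.
#' @export
apply_low_density_texture <- function(image, mask, reduction_range,
                                      seed = 1L, erode_radius_px = 2L) {
  stopifnot(identical(dim(image), dim(mask)),
            length(reduction_range) == 2, all(reduction_range >= 0),
            reduction_range[1] <= reduction_range[2])
  interior <- erode_binary(matrix(mask > 0, nrow(mask), ncol(mask)),
                           erode_radius_px)
  n <- sum(interior)
  if (n == 0) {
    warning("interior empty after erosion; image unchanged")
    return(image)
  }
  set.seed(seed)
  image[interior] <- image[interior] -
    stats::runif(n, reduction_range[1], reduction_range[2])
  image
}

#' Mock fracture detector with calibrated operating characteristics
#'
#' Stands in for a trained bounding-box detector: every vertebra draws a
#' confidence from a logit-normal distribution whose location is set by
#' closed-form quantile matching so that thresholding the confidence at 0.5
#' attains the requested sensitivity (fractured vertebrae) and specificity
#' (normal vertebrae) in expectation. A box (the truth box with a small
#' jitter, in YOLO-normalized coordinates) is emitted whenever the confidence
#' reaches `emit_floor`; vertebrae below it yield no box at all.
#'
#' @param phantom A `vcf_phantom` (or its `truth` data frame carrying an
#'   `image_dim` attribute).
#' @param sens_target,spec_target Target sensitivity/specificity at the 0.5
#'   operating point, in (0, 1\].
#' @param seed Integer seed.
#' @param sd Spread of the latent logit-normal scores.
#' @param emit_floor Minimum confidence for a box to be emitted.
#' @param jitter Uniform half-width of the relative box-coordinate jitter.
#' @return Data frame of boxes: `vertebra`, `class` (0), `cx`, `cy`, `w`,
#'   `h`, `conf`, normalized to the image size.
#' @export
mock_detector <- function(phantom, sens_target = 0.83, spec_target = 0.96,
                          seed = 1L, sd = 1, emit_floor = 0.02,
                          jitter = 0.01) {
  if (inherits(phantom, "vcf_phantom")) {
    truth <- phantom$truth
    dims <- dim(phantom$mask)
  } else {
    truth <- phantom
    dims <- attr(truth, "image_dim")
    if (is.null(dims)) stop("truth table lacks an image_dim attribute")
  }
  stopifnot(sens_target > 0, sens_target <= 1, spec_target > 0, spec_target <= 1)
  set.seed(seed)
  q <- function(p) max(min(stats::qnorm(p), 8), -8)
  mu <- ifelse(truth$fractured, sd * q(sens_target), sd * q(1 - spec_target))
  conf <- stats::plogis(stats::rnorm(nrow(truth), mu, sd))
  cx <- (truth$x0 + truth$x1 + 1) / 2 / dims[2]
  cy <- (truth$y0 + truth$y1 + 1) / 2 / dims[1]
  w <- (truth$x1 - truth$x0 + 1) / dims[2]
  h <- (truth$y1 - truth$y0 + 1) / dims[1]
  n <- nrow(truth)
  out <- data.frame(
    vertebra = truth$vertebra,
    class = 0L,
    cx = pmin(pmax(cx + stats::runif(n, -jitter, jitter) * w, 0), 1),
    cy = pmin(pmax(cy + stats::runif(n, -jitter, jitter) * h, 0), 1),
    w = w * (1 + stats::runif(n, -jitter, jitter)),
    h = h * (1 + stats::runif(n, -jitter, jitter)),
    conf = conf
  )
  out[out$conf >= emit_floor, , drop = FALSE]
}

#' Cohort-scale phantom specification
#'
#' Samples a deformity plan for a cohort of vertebrae: each fractured
#' vertebra receives a deformity class (wedge-dominant mix, with biconcave
#' and crush minorities) and a diagnostically positive target height loss
#' ratio; fracture positions are shuffled through the stack. The default
#' sizes match a test cohort of 99 fractured and 882 normal vertebrae.
#'
#' @param n_fractured,n_normal Cohort composition.
#' @param seed Integer seed driving the sampling.
#' @param height_range_mm Range of posterior heights drawn per vertebra.
#' @param hlr_range Range of target height loss ratios for fractures.
#' @param class_probs Probabilities for wedge/biconcave/crush.
#' @param ... Passed to [phantom_spec()].
#' @return A `phantom_spec` for `n_fractured + n_normal` vertebrae.
#' @export
cohort_spec <- function(n_fractured = 99L, n_normal = 882L, seed = 1L,
                        height_range_mm = c(18, 28),
                        hlr_range = c(0.26, 0.55),
                        class_probs = c(wedge = 0.6, biconcave = 0.25, crush = 0.15),
                        ...) {
  n <- n_fractured + n_normal
  set.seed(seed)
  heights <- stats::runif(n, height_range_mm[1], height_range_mm[2])
  frac_idx <- sort(sample.int(n, n_fractured))
  plan <- data.frame(
    vertebra = frac_idx,
    class = sample(names(class_probs), n_fractured, replace = TRUE,
                   prob = class_probs),
    target_hlr = stats::runif(n_fractured, hlr_range[1], hlr_range[2])
  )
  phantom_spec(n, base_posterior_height_mm = heights,
               deformity_plan = plan, seed = seed, ...)
}
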