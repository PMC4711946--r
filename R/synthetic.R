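#' Specification of a synthetic trichrome vessel image
#'
#' Describes a simulated Masson's-trichrome-like cross-section: a bright
#' near-white background and lumen, an annular vessel wall whose pixels are
#' split between a reddish smooth-muscle color family and a blue/green
#' matrix family, plus the defects real slides carry — dark tissue folds
#' crossing the wall, blood-colored blobs, and small dust specks outside the
#' wall and inside the lumen.
#'
#' Default palettes mimic the trichrome contrast (muscle red: positive a*;
#' collagenous matrix blue/green: negative a* and b*); channel noise of
#' sd 2.5 CIELab units reflects the within-stain color variability of a
#' single section.
#'
#' @param height,width Image size in pixels.
#' @param center Wall center `(row, col)`; defaults to the image center.
#' @param inner_radius,outer_radius Annulus radii in pixels
#'   (0 < inner < outer).
#' @param smf_fraction Target muscle fraction of the wall, in \[0, 1\].
#' @param smf_color,ecm_color,blood_color,background_color L*a*b* triples.
#' @param color_noise_sd Per-channel Gaussian color noise, CIELab units.
#' @param n_folds,n_blood,n_dust Defect counts.
#' @param seed RNG seed; the image is a pure function of the spec.
#' @return A list of class `vessel_spec`.
#' @export
vessel_spec <- function(height = 192L, width = 192L, center = NULL,
                        inner_radius = 38, outer_radius = 78,
                        smf_fraction = 0.5,
                        smf_color = c(55, 35, 15),
                        ecm_color = c(60, -20, -15),
                        blood_color = c(35, 45, 25),
                        background_color = c(96, 0, 2),
                        color_noise_sd = 2.5,
                        n_folds = 1L, n_blood = 2L, n_dust = 10L,
                        seed = 1L) {
  stopifnot(height >= 1, width >= 1, inner_radius > 0,
            outer_radius > inner_radius,
            smf_fraction >= 0, smf_fraction <= 1, color_noise_sd >= 0,
            n_folds >= 0, n_blood >= 0, n_dust >= 0)
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (outer_radius > min(center[1], height - center[1] + 1,
                         center[2], width - center[2] + 1)) {
    stop("outer radius exceeds image bounds")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = center, inner_radius = inner_radius,
                 outer_radius = outer_radius, smf_fraction = smf_fraction,
                 smf_color = smf_color, ecm_color = ecm_color,
                 blood_color = blood_color,
                 background_color = background_color,
                 color_noise_sd = color_noise_sd,
                 n_folds = as.integer(n_folds), n_blood = as.integer(n_blood),
                 n_dust = as.integer(n_dust), seed = as.integer(seed)),
            class = "vessel_spec")
}

#' Generate a synthetic vessel image with ground truth
#'
#' Renders the section described by a [vessel_spec()] and returns both the
#' 8-bit RGB image and the ground-truth masks, so that every pipeline stage
#' can be validated against known answers. Muscle vs matrix within the wall
#' is assigned by thresholding a low-frequency smooth noise field at the
#' empirical quantile matching `smf_fraction`, producing connected blotches
#' (as in stained tissue) whose realized fraction matches the target to
#' within one pixel's worth of quantile resolution.
#'
#' @param spec A [vessel_spec()].
#' @return List with `image` (`H x W x 3` integer RGB array) and `truth`, a
#'   list of logical masks (`wall_mask`, `smf_mask`, `ecm_mask`, `fold_mask`,
#'   `blood_mask`, `dust_mask`) plus `true_smf_fraction` (realized fraction
#'   of the wall before defect overpainting).
#' @export
generate_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "vessel_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    h <- spec$height; w <- spec$width
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    rr <- sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2)
    wall <- rr > spec$inner_radius & rr <= spec$outer_radius
    lumen <- rr <= spec$inner_radius

    # blotchy muscle/matrix split via a smooth random field
    field <- smooth_field(rows, cols)
    wall_vals <- field[wall]
    smf <- matrix(FALSE, h, w)
    if (spec$smf_fraction >= 1) {
      smf[wall] <- TRUE
    } else if (spec$smf_fraction > 0) {
      q <- stats::quantile(wall_vals, 1 - spec$smf_fraction, names = FALSE,
                           type = 1)
      smf[wall] <- wall_vals > q
      # quantile ties can undershoot; realized fraction stays within 1/n_wall
      if (mean(smf[wall]) < spec$smf_fraction - 1 / sum(wall)) {
        smf[wall] <- wall_vals >= q
      }
    }
    ecm <- wall & !smf
    true_frac <- if (any(wall)) mean(smf[wall]) else NA_real_

    L <- matrix(spec$background_color[1], h, w)
    a <- matrix(spec$background_color[2], h, w)
    b <- matrix(spec$background_color[3], h, w)
    paint <- function(mask, col) {
      L[mask] <<- col[1]; a[mask] <<- col[2]; b[mask] <<- col[3]
    }
    paint(smf, spec$smf_color)
    paint(ecm, spec$ecm_color)

    # folds: dark wedges crossing the wall radially
    fold_mask <- matrix(FALSE, h, w)
    if (spec$n_folds > 0) {
      theta <- atan2(rows - spec$center[1], cols - spec$center[2])
      for (i in seq_len(spec$n_folds)) {
        th0 <- stats::runif(1, -pi, pi)
        dth <- stats::runif(1, 0.03, 0.06)
        ang <- abs(((theta - th0 + pi) %% (2 * pi)) - pi)
        fold_mask <- fold_mask | (wall & ang < dth)
      }
      paint(fold_mask, c(10, 2, 2))
    }

    # blood blobs anywhere inside the outer boundary
    blood_mask <- matrix(FALSE, h, w)
    for (i in seq_len(spec$n_blood)) {
      rad <- stats::runif(1, 3, 6)
      rpos <- stats::runif(1, 0, spec$outer_radius - rad)
      ang <- stats::runif(1, -pi, pi)
      cy <- spec$center[1] + rpos * sin(ang)
      cx <- spec$center[2] + rpos * cos(ang)
      blob <- (rows - cy)^2 + (cols - cx)^2 <= rad^2
      blood_mask <- blood_mask | blob
    }
    if (any(blood_mask)) paint(blood_mask, spec$blood_color)

    # dust specks of 1-5 px in the lumen and exterior
    dust_mask <- matrix(FALSE, h, w)
    outside <- !wall & !blood_mask &
      (rr < spec$inner_radius - 4 | rr > spec$outer_radius + 4)
    out_idx <- which(outside)
    if (spec$n_dust > 0 && length(out_idx) > 0) {
      for (i in seq_len(spec$n_dust)) {
        p <- sample(out_idx, 1)
        npx <- sample(1:5, 1)
        r0 <- ((p - 1) %% h) + 1; c0 <- ((p - 1) %/% h) + 1
        drs <- c(0, 1, 0, -1, 0); dcs <- c(0, 0, 1, 0, -1)
        for (s in seq_len(npx)) {
          r1 <- r0 + drs[s]; c1 <- c0 + dcs[s]
          if (r1 >= 1 && r1 <= h && c1 >= 1 && c1 <= w && outside[r1, c1]) {
            dust_mask[r1, c1] <- TRUE
          }
        }
      }
      paint(dust_mask, c(45, 3, 8))
    }

    if (spec$color_noise_sd > 0) {
      L <- L + matrix(stats::rnorm(h * w, 0, spec$color_noise_sd), h, w)
      a <- a + matrix(stats::rnorm(h * w, 0, spec$color_noise_sd), h, w)
      b <- b + matrix(stats::rnorm(h * w, 0, spec$color_noise_sd), h, w)
    }
    L <- pmin(pmax(L, 0), 100)

    defect <- fold_mask | blood_mask
    truth <- list(
      wall_mask = wall,
      smf_mask = smf & !defect,
      ecm_mask = ecm & !defect,
      fold_mask = fold_mask,
      blood_mask = blood_mask,
      dust_mask = dust_mask,
      lumen_mask = lumen,
      true_smf_fraction = true_frac
    )
    list(image = lab_to_rgb(new_lab_image(L, a, b)), truth = truth)
  })
}

# Smooth low-frequency random field (sum of random cosines), standardized.
smooth_field <- function(rows, cols) {
  f <- matrix(0, nrow(rows), ncol(rows))
  for (k in 1:6) {
    fr <- stats::runif(1, 0.02, 0.08)
    ang <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::runif(1, 0.5, 1) *
      cos(2 * pi * fr * (rows * sin(ang) + cols * cos(ang)) + ph)
  }
  f + stats::rnorm(length(f), 0, 0.05)
}

#' Generate per-sample ratio tables for group comparisons
#'
#' Draws normalized muscle-area ratios for several vein-segment groups from
#' truncated normal distributions on \[0, 1\], emulating the per-sample
#' measurement table that feeds the group statistics. The matrix ratio is
#' drawn around the complement so that the two ratios sum to just under 1,
#' as on defect-free sections where the background cluster captures only a
#' few wall pixels.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param group_means Named numeric vector (same names) of mean `ratio_SMF`
#'   per group, in \[0, 1\].
#' @param sd Common within-group standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Data frame with columns `sample_id`, `group`, `ratio_SMF`,
#'   `ratio_ECM`.
#' @export
generate_group_samples <- function(n_per_group, group_means, sd = 0.08,
                                   seed = 1L) {
  stopifnot(length(n_per_group) == length(group_means),
            !is.null(names(n_per_group)),
            all(names(n_per_group) %in% names(group_means)),
            all(group_means >= 0 & group_means <= 1), sd >= 0)
  with_preserved_rng({
    set.seed(as.integer(seed))
    rows <- lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      smf <- rtruncnorm01(n, group_means[[g]], sd)
      ecm <- rtruncnorm01(n, 0.95 - group_means[[g]], sd)
      ecm <- pmin(ecm, 1 - smf)
      data.frame(sample_id = sprintf("%s_%02d", g, seq_len(n)),
                 group = g, ratio_SMF = smf, ratio_ECM = ecm,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Normal truncated to [0, 1] by inverse-CDF sampling; sd = 0 returns the mean.
rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(1, pmax(0, mean)), n))
  lo <- stats::pnorm((0 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}
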