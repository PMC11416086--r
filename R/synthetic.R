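# Synthetic water-sensitive-paper generator with exact ground truth.
#
# Renders dark, near-elliptical stains on a light background, optionally
# punches bright glare holes strictly inside stains, then adds Gaussian
# sensor noise. The ground-truth mask is the pre-glare, pre-noise stain
# footprint, counted in whole pixels (no anti-aliasing), so truth coverage
# and counts are exact. Stamps are morphologically regularised (closed with
# the default 3x3 element at render time) and separated by a minimum
# Chebyshev gap, so the analysis pipeline's closing step neither distorts
# shapes nor bridges neighbours, and exact metric recovery is well-posed.

#' Specification of a synthetic WSP image
#'
#' Defaults emulate a 76 x 26 mm card scanned at 96 DPI (287 x 98 px) with
#' bright paper (mean gray 210), dark stains (mean 60), sensor noise of
#' sigma 5 gray levels, and 1-px-radius glare holes on 30% of droplets.
#' Droplet radii follow a log-normal (spray deposit size spectra are
#' right-skewed), truncated to \[1, min(width, height) / 4\].
#'
#' @param width_px,height_px Canvas size in pixels (defaults 287 x 98).
#' @param dpi Scan resolution carried on the generated image (default 96).
#' @param n_droplets Number of stains to place (default 15).
#' @param radius_meanlog,radius_sdlog Log-normal parameters of the droplet
#'   radius in px (defaults log(2.5), 0.45).
#' @param ellipticity_range Axis-ratio interval, default c(1, 1.5); area is
#'   preserved (major = r sqrt(q), minor = r / sqrt(q)).
#' @param background_mean,droplet_mean Gray levels of paper and stain
#'   (defaults 210 and 60; stains must be darker than paper).
#' @param noise_sigma Additive Gaussian noise sd in gray levels (default 5).
#' @param glare_hole_prob Per-droplet probability of one glare hole
#'   (default 0.3).
#' @param glare_hole_radius_px Hole radius; holes are strict discs
#'   (dx^2 + dy^2 <= r^2), so the default radius 1 is a 5-px plus, strictly
#'   smaller than the default 3x3 closing element. Default 1.
#' @param min_center_distance_px Minimum distance between stain centres;
#'   0 (default) imposes no centre constraint.
#' @param min_gap_px Minimum Chebyshev gap enforced between stamped stains
#'   (default 3, enough that closing never bridges neighbours); 0 permits
#'   adjacency.
#' @param seed Integer RNG seed (required).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(width_px = 287, height_px = 98, dpi = 96,
                           n_droplets = 15,
                           radius_meanlog = log(2.5), radius_sdlog = 0.45,
                           ellipticity_range = c(1, 1.5),
                           background_mean = 210, droplet_mean = 60,
                           noise_sigma = 5, glare_hole_prob = 0.3,
                           glare_hole_radius_px = 1,
                           min_center_distance_px = 0, min_gap_px = 3,
                           seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_scalar_number(width_px, "width_px", 1, Inf, integer = TRUE)
  check_scalar_number(height_px, "height_px", 1, Inf, integer = TRUE)
  check_scalar_number(dpi, "dpi", lower = .Machine$double.eps)
  check_scalar_number(n_droplets, "n_droplets", 0, Inf, integer = TRUE)
  check_scalar_number(radius_meanlog, "radius_meanlog")
  check_scalar_number(radius_sdlog, "radius_sdlog", 0, Inf)
  stopifnot(length(ellipticity_range) == 2L,
            ellipticity_range[1] >= 1, diff(ellipticity_range) >= 0)
  check_scalar_number(background_mean, "background_mean", 0, 255,
                      integer = TRUE)
  check_scalar_number(droplet_mean, "droplet_mean", 0, 255, integer = TRUE)
  if (droplet_mean >= background_mean) {
    stop("`droplet_mean` must be below `background_mean` ",
         "(dark stains on light paper)", call. = FALSE)
  }
  check_scalar_number(noise_sigma, "noise_sigma", 0, Inf)
  check_scalar_number(glare_hole_prob, "glare_hole_prob", 0, 1)
  check_scalar_number(glare_hole_radius_px, "glare_hole_radius_px", 1, Inf,
                      integer = TRUE)
  check_scalar_number(min_center_distance_px, "min_center_distance_px",
                      0, Inf)
  check_scalar_number(min_gap_px, "min_gap_px", 0, Inf, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         dpi = as.numeric(dpi), n_droplets = as.integer(n_droplets),
         radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
         ellipticity_range = as.numeric(ellipticity_range),
         background_mean = as.integer(background_mean),
         droplet_mean = as.integer(droplet_mean),
         noise_sigma = noise_sigma, glare_hole_prob = glare_hole_prob,
         glare_hole_radius_px = as.integer(glare_hole_radius_px),
         min_center_distance_px = min_center_distance_px,
         min_gap_px = as.integer(min_gap_px), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Rasterise one rotated ellipse as a regularised local stamp.
# Returns a logical matrix of side 2*halfw+1 centred on the ellipse centre.
make_stamp <- function(r, q, theta, regularise = TRUE) {
  a <- r * sqrt(q)
  b <- r / sqrt(q)
  halfw <- as.integer(ceiling(a)) + 1L
  d <- seq(-halfw, halfw)
  ct <- cos(theta)
  st <- sin(theta)
  inside <- outer(d, d, function(dy, dx) {
    u <- (dx * ct + dy * st) / a
    v <- (-dx * st + dy * ct) / b
    u * u + v * v <= 1
  })
  if (regularise) inside <- close_matrix(inside, structuring_element())
  inside
}

#' Generate a synthetic WSP image with exact ground truth
#'
#' Places `n_droplets` stamped ellipses by rejection sampling (bounded at
#' 10,000 attempts per droplet; if the canvas fills up, fewer are placed
#' with a warning and `n_droplets_placed` records the achieved count),
#' punches glare holes, then adds noise. Ground truth (mask, count,
#' coverage, per-droplet geometry) is computed before glare and noise:
#' glare is a scan artifact to be repaired, not true background.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (a [gray_image()]) and `truth`, a `wsp_truth`
#'   list: `mask` (`droplet_mask`), `n_droplets_placed`, `coverage_pct`,
#'   `total_area_px`, `per_droplet` (centre, axes, angle, area per stain).
#' @examples
#' g <- generate_wsp(synthetic_spec(n_droplets = 5, seed = 42))
#' g$truth$coverage_pct
#' @export
generate_wsp <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height_px
  w <- spec$width_px
  rmax <- min(w, h) / 4
  # grossly unsatisfiable request: expected stain demand exceeds the canvas
  expected_demand <- spec$n_droplets *
    pi * exp(2 * spec$radius_meanlog + 2 * spec$radius_sdlog^2)
  if (expected_demand > 0.85 * w * h) {
    stop(sprintf(
      "unsatisfiable spec: ~%.0f px of stain demanded on a %d-px canvas",
      expected_demand, w * h), call. = FALSE)
  }

  with_seed(spec$seed, {
    truth <- matrix(FALSE, h, w)
    forbid <- matrix(FALSE, h, w)
    gap_selem <- if (spec$min_gap_px > 0) {
      structuring_element("square", spec$min_gap_px)
    }
    per <- vector("list", spec$n_droplets)
    centers <- matrix(numeric(0), 0, 2)
    placed <- 0L
    demanded <- 0

    for (i in seq_len(spec$n_droplets)) {
      repeat {   # truncated log-normal radius
        r <- stats::rlnorm(1, spec$radius_meanlog, spec$radius_sdlog)
        if (r >= 1 && r <= rmax) break
      }
      q <- stats::runif(1, spec$ellipticity_range[1],
                        spec$ellipticity_range[2])
      theta <- stats::runif(1, 0, pi)
      stamp <- make_stamp(r, q, theta)
      halfw <- (nrow(stamp) - 1L) %/% 2L
      sarea <- sum(stamp)
      demanded <- demanded + sarea
      if (demanded > 0.85 * w * h) {
        stop(sprintf(
          "unsatisfiable spec: demanded stain area exceeds canvas after %d placed",
          placed), call. = FALSE)
      }
      loc <- which(stamp, arr.ind = TRUE)
      dr <- loc[, 1] - halfw - 1L
      dc <- loc[, 2] - halfw - 1L
      margin <- halfw + 2L
      if (h - 2L * margin < 0L || w - 2L * margin < 0L) break  # cannot fit
      ok <- FALSE
      for (attempt in seq_len(10000L)) {
        cr <- sample.int(h - 2L * margin + 1L, 1L) + margin - 1L + 1L
        cc <- sample.int(w - 2L * margin + 1L, 1L) + margin - 1L + 1L
        if (spec$min_center_distance_px > 0 && nrow(centers) > 0) {
          dmin <- min(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2))
          if (dmin < spec$min_center_distance_px) next
        }
        idx <- (cc + dc - 1L) * h + (cr + dr)
        if (any(forbid[idx])) next
        ok <- TRUE
        break
      }
      if (!ok) break
      truth[idx] <- TRUE
      if (is.null(gap_selem)) {
        forbid[idx] <- TRUE
      } else {
        # pad before dilating so the forbidden zone is never clipped
        g <- spec$min_gap_px
        sz <- nrow(stamp)
        padded <- matrix(FALSE, sz + 2L * g, sz + 2L * g)
        padded[(g + 1L):(g + sz), (g + 1L):(g + sz)] <- stamp
        dil <- dilate_logical(padded, selem_offsets(gap_selem))
        gloc <- which(dil, arr.ind = TRUE)
        gr <- cr + (gloc[, 1] - halfw - g - 1L)
        gc <- cc + (gloc[, 2] - halfw - g - 1L)
        keep <- gr >= 1L & gr <= h & gc >= 1L & gc <= w
        forbid[(gc[keep] - 1L) * h + gr[keep]] <- TRUE
      }
      placed <- placed + 1L
      centers <- rbind(centers, c(cr, cc))
      per[[placed]] <- data.frame(
        center_row = cr, center_col = cc,
        major_axis_px = r * sqrt(q), minor_axis_px = r / sqrt(q),
        angle_rad = theta, area_px = sarea,
        stamp_halfw = halfw, stamp_i = I(list(idx)))
    }
    if (placed < spec$n_droplets) {
      warning(sprintf("placed %d of %d droplets before the canvas filled up",
                      placed, spec$n_droplets), call. = FALSE)
    }

    img <- matrix(as.numeric(spec$background_mean), h, w)
    img[truth] <- spec$droplet_mean

    # Glare: one bright hole per affected droplet, strictly interior so
    # closing with the default element repairs it exactly.
    ghr <- spec$glare_hole_radius_px
    hole_d <- seq(-ghr, ghr)
    hole_off <- which(outer(hole_d, hole_d,
                            function(dy, dx) dy^2 + dx^2 <= ghr^2),
                      arr.ind = TRUE)
    hdr <- hole_off[, 1] - ghr - 1L
    hdc <- hole_off[, 2] - ghr - 1L
    interior_selem <- structuring_element("square", ghr + 1L)
    for (i in seq_len(placed)) {
      if (stats::runif(1) >= spec$glare_hole_prob) next
      halfw <- per[[i]]$stamp_halfw
      sz <- 2L * halfw + 1L
      # rebuild the local stamp from the stored absolute indices
      abs_idx <- per[[i]]$stamp_i[[1]]
      ar <- ((abs_idx - 1L) %% h) + 1L
      ac <- ((abs_idx - 1L) %/% h) + 1L
      stamp <- matrix(FALSE, sz, sz)
      stamp[cbind(ar - per[[i]]$center_row + halfw + 1L,
                  ac - per[[i]]$center_col + halfw + 1L)] <- TRUE
      core <- erode_logical(stamp, selem_offsets(interior_selem))
      cand <- which(core)
      if (length(cand) == 0L) next
      pick <- cand[sample.int(length(cand), 1L)]
      pr <- ((pick - 1L) %% sz) + 1L - halfw - 1L + per[[i]]$center_row
      pc <- ((pick - 1L) %/% sz) + 1L - halfw - 1L + per[[i]]$center_col
      img[(pc + hdc - 1L) * h + (pr + hdr)] <- spec$background_mean
    }

    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    }
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)

    per_droplet <- if (placed > 0L) {
      df <- do.call(rbind, per[seq_len(placed)])
      df$stamp_halfw <- NULL
      df$stamp_i <- NULL
      df
    } else {
      data.frame(center_row = integer(0), center_col = integer(0),
                 major_axis_px = numeric(0), minor_axis_px = numeric(0),
                 angle_rad = numeric(0), area_px = integer(0))
    }
    truth_obj <- structure(
      list(mask = droplet_mask(truth),
           n_droplets_placed = placed,
           coverage_pct = 100 * sum(truth) / (h * w),
           total_area_px = as.integer(sum(truth)),
           per_droplet = per_droplet),
      class = "wsp_truth")
    list(image = gray_image(img, dpi = spec$dpi), truth = truth_obj)
  })
}

#' @export
print.wsp_truth <- function(x, ...) {
  cat(sprintf("<wsp_truth> %d droplets, PA = %d px, coverage = %.3f%%\n",
              x$n_droplets_placed, x$total_area_px, x$coverage_pct))
  invisible(x)
}

# Per-group generation settings. Denser groups use a larger canvas (higher
# scan DPI) so the printed PA intervals are attainable at realistic
# coverage: a 287 x 98 canvas has only 28,126 px in total.
panel_group_params <- function(group) {
  switch(group,
    sparse = list(w = 287L, h = 98L, dpi = 96, meanlog = log(2.5),
                  sdlog = 0.45, pa_target = c(800, 5500), gap = 3L,
                  lo = 0, hi = 12000, hi_closed = TRUE),
    medium = list(w = 766L, h = 262L, dpi = 256, meanlog = log(5),
                  sdlog = 0.40, pa_target = c(14000, 26000), gap = 2L,
                  lo = 12000, hi = 40000, hi_closed = TRUE),
    dense  = list(w = 1149L, h = 393L, dpi = 384, meanlog = log(7),
                  sdlog = 0.35, pa_target = c(45000, 70000), gap = 2L,
                  lo = 40000, hi = 90000, hi_closed = FALSE)
  )
}

pa_in_group <- function(pa, gp) {
  pa > gp$lo && (if (gp$hi_closed) pa <= gp$hi else pa < gp$hi)
}

#' Generate a panel of synthetic WSP images for a deposition group
#'
#' Draws image specifications whose realised ground-truth droplet pixel
#' area (PA) falls inside the group's interval - sparse: PA <= 12,000;
#' medium: 12,000 < PA <= 40,000; dense: 40,000 < PA < 90,000 - resampling
#' (with the droplet count adjusted toward the target) until the interval
#' is hit, at most 1,000 draws per image. Panels use noise sigma 5 and
#' glare holes on, the realistic synthetic benchmarking condition.
#'
#' @param group `"sparse"`, `"medium"` or `"dense"`.
#' @param n_images Positive number of images.
#' @param seed Integer master seed; the whole panel is a deterministic
#'   function of it.
#' @return List of `n_images` elements, each a list with `image` and
#'   `truth` as from [generate_wsp()].
#' @examples
#' panel <- generate_group_panel("sparse", n_images = 2, seed = 7)
#' sapply(panel, function(x) x$truth$total_area_px)   # all <= 12000
#' @export
generate_group_panel <- function(group = c("sparse", "medium", "dense"),
                                 n_images, seed) {
  group <- match.arg(group)
  check_scalar_number(n_images, "n_images", 1, Inf, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  gp <- panel_group_params(group)
  mean_area <- pi * exp(2 * gp$meanlog + 2 * gp$sdlog^2)

  draws <- with_seed(seed, list(
    targets = stats::runif(n_images, gp$pa_target[1], gp$pa_target[2]),
    subseeds = sample.int(2^30, n_images)
  ))

  out <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    target <- draws$targets[i]
    n <- max(1L, as.integer(round(target / mean_area)))
    got <- NULL
    for (attempt in seq_len(1000L)) {
      spec <- synthetic_spec(
        width_px = gp$w, height_px = gp$h, dpi = gp$dpi, n_droplets = n,
        radius_meanlog = gp$meanlog, radius_sdlog = gp$sdlog,
        noise_sigma = 5, glare_hole_prob = 0.3, min_gap_px = gp$gap,
        seed = (draws$subseeds[i] + attempt) %% .Machine$integer.max)
      cand <- suppressWarnings(generate_wsp(spec))
      pa <- cand$truth$total_area_px
      if (pa_in_group(pa, gp)) {
        got <- cand
        break
      }
      # steer the droplet count toward the target PA
      n_new <- max(1L, as.integer(round(n * target / max(pa, 1))))
      n <- if (n_new == n) n + (if (pa < target) 1L else -1L) else n_new
      n <- max(1L, n)
    }
    if (is.null(got)) {
      stop(sprintf("could not hit the %s PA interval in 1000 draws", group),
           call. = FALSE)
    }
    out[[i]] <- got
  }
  names(out) <- sprintf("img%03d", seq_len(n_images))
  out
}
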