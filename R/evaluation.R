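# Relative-error benchmarking of the three segmentation methods against
# reference (manual or synthetic-truth) coverage and density values,
# aggregated by PA group.

#' Absolute relative error (%)
#'
#' 100 * |measured - reference| / reference. The benchmarking protocol
#' plots unsigned relative errors, so the absolute value is taken; images
#' with zero reference are excluded from summaries (a relative error
#' against zero is undefined).
#'
#' @param measured,reference Numeric vectors (recycled); `reference` must
#'   be positive.
#' @return Non-negative percentage error(s).
#' @examples
#' relative_error(103, 100)   # 3
#' relative_error(97, 100)    # 3
#' @export
relative_error <- function(measured, reference) {
  if (!is.numeric(measured) || !is.numeric(reference)) {
    stop("`measured` and `reference` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("`reference` must be positive", call. = FALSE)
  }
  100 * abs(measured - reference) / reference
}

#' Build a reference record from synthetic ground truth
#'
#' Converts a `wsp_truth` object into the reference row used by
#' [benchmark_methods()], standing in for manual annotation.
#'
#' @param truth A `wsp_truth` from [generate_wsp()].
#' @param img The matching [gray_image()] (for the physical area).
#' @param image_id Identifier string.
#' @return One-row data frame: `image_id`, `true_coverage_pct`,
#'   `true_density`, `pa_group`.
#' @export
truth_reference <- function(truth, img, image_id) {
  stopifnot(inherits(truth, "wsp_truth"), inherits(img, "gray_image"))
  data.frame(
    image_id = image_id,
    true_coverage_pct = truth$coverage_pct,
    true_density = truth$n_droplets_placed / physical_area_cm2(img),
    pa_group = classify_pa_group(truth$total_area_px),
    stringsAsFactors = FALSE
  )
}

#' Benchmark segmentation methods against reference values
#'
#' Runs [analyze_image()] for every image x method combination, computes
#' per-image absolute relative errors of coverage and density against the
#' reference table, and averages them per (method, PA group). Images
#' without a reference row are skipped with a warning; images whose
#' reference coverage or density is zero are excluded with a warning.
#'
#' @param images Named list of [gray_image()] objects; names are image ids.
#' @param references Data frame with columns `image_id`,
#'   `true_coverage_pct`, `true_density`, `pa_group`.
#' @param methods Character subset of `c("fixed", "otsu", "genetic_otsu")`.
#' @param ga_config A [ga_config()], required when `"genetic_otsu"` is
#'   among the methods (the same seeded configuration is applied to every
#'   image, keeping the run deterministic).
#' @param selem,min_droplet_area_px,connectivity Passed to
#'   [analyze_image()].
#' @return Data frame (`error_summary`): `method`, `pa_group`,
#'   `mean_rel_err_coverage_pct`, `mean_rel_err_density_pct`, `n_images`.
#' @export
benchmark_methods <- function(images, references,
                              methods = c("fixed", "otsu", "genetic_otsu"),
                              ga_config = NULL,
                              selem = structuring_element(),
                              min_droplet_area_px = 2, connectivity = 8) {
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a non-empty named list of gray_image objects",
         call. = FALSE)
  }
  if (is.null(names(images)) || any(!nzchar(names(images)))) {
    stop("`images` must be named by image_id", call. = FALSE)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  need <- c("image_id", "true_coverage_pct", "true_density", "pa_group")
  if (!is.data.frame(references) || !all(need %in% names(references))) {
    stop("`references` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("genetic_otsu" %in% methods && is.null(ga_config)) {
    stop("`ga_config` is required when benchmarking \"genetic_otsu\"",
         call. = FALSE)
  }

  rows <- list()
  for (id in names(images)) {
    ref <- references[references$image_id == id, , drop = FALSE]
    if (nrow(ref) == 0L) {
      warning(sprintf("no reference for image %s; skipped", id),
              call. = FALSE)
      next
    }
    ref <- ref[1L, ]
    if (ref$true_coverage_pct <= 0 || ref$true_density <= 0) {
      warning(sprintf("zero-truth reference for image %s; excluded", id),
              call. = FALSE)
      next
    }
    for (method in methods) {
      rep <- analyze_image(
        images[[id]], method = method, selem = selem,
        min_droplet_area_px = min_droplet_area_px,
        ga_config = if (method == "genetic_otsu") ga_config,
        connectivity = connectivity)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, method = method, pa_group = ref$pa_group,
        rel_err_coverage = relative_error(rep$coverage_pct,
                                          ref$true_coverage_pct),
        rel_err_density = relative_error(rep$density_per_cm2,
                                         ref$true_density),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    stop("no image had a usable reference", call. = FALSE)
  }
  per_image <- do.call(rbind, rows)
  agg <- stats::aggregate(
    cbind(rel_err_coverage, rel_err_density) ~ method + pa_group,
    data = per_image, FUN = mean)
  counts <- stats::aggregate(image_id ~ method + pa_group, data = per_image,
                             FUN = length)
  out <- merge(agg, counts, by = c("method", "pa_group"), sort = TRUE)
  names(out) <- c("method", "pa_group", "mean_rel_err_coverage_pct",
                  "mean_rel_err_density_pct", "n_images")
  out <- out[order(out$method, out$pa_group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_image") <- per_image
  class(out) <- c("error_summary", "data.frame")
  out
}
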