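# Gray-level histogram, fixed-threshold and exhaustive Otsu segmentation.

#' The fixed 8-bit WSP segmentation threshold
#'
#' The conventional fixed cut-off for WSP stains is 0.60 on a normalized
#' \[0, 1\] intensity scale; on 8-bit images this is
#' `round(0.60 * 255) = 153`.
#'
#' @return Integer threshold, 153.
#' @export
fixed_wsp_threshold <- function() as.integer(round(0.60 * 255))

#' Gray-level histogram of an image
#'
#' Empirical probability distribution p_i over the 256 gray levels,
#' p_i = (pixels with value i) / n.
#'
#' @param img A [gray_image()].
#' @return A `gray_histogram`: list with `p` (256 probabilities for levels
#'   0..255), `counts` (integer counts) and `n_pixels`.
#' @examples
#' h <- compute_histogram(gray_image(matrix(c(0L, 0L, 255L, 255L), 2)))
#' h$p[c(1, 256)]   # 0.5 each at levels 0 and 255
#' @export
compute_histogram <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = 256L)
  gray_histogram(counts = counts)
}

#' Construct a gray-level histogram directly
#'
#' Builds a `gray_histogram` from raw level counts, or from probabilities
#' plus a pixel total (probabilities must correspond to integral counts).
#'
#' @param counts Integer vector of 256 non-negative level counts.
#' @param p Alternative to `counts`: 256 probabilities summing to 1.
#' @param n_pixels Required with `p`: the pixel total.
#' @return A `gray_histogram` object.
#' @export
gray_histogram <- function(counts = NULL, p = NULL, n_pixels = NULL) {
  if (is.null(counts)) {
    if (is.null(p) || is.null(n_pixels)) {
      stop("supply `counts`, or `p` together with `n_pixels`", call. = FALSE)
    }
    if (length(p) != 256L || any(p < 0)) {
      stop("`p` must be 256 non-negative probabilities", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("probabilities must sum to 1", call. = FALSE)
    }
    counts <- p * n_pixels
    if (any(abs(counts - round(counts)) > 1e-6)) {
      stop("`p` * `n_pixels` must be integral", call. = FALSE)
    }
    counts <- as.integer(round(counts))
  }
  if (length(counts) != 256L || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must be 256 non-negative integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  n <- sum(counts)
  if (n < 1L) stop("histogram is empty", call. = FALSE)
  structure(list(p = counts / n, counts = counts, n_pixels = n),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("<gray_histogram> %d pixels, %d occupied levels in [%d, %d]\n",
              x$n_pixels, length(occ), min(occ), max(occ)))
  invisible(x)
}

# Between-class variance curve over all 256 candidate thresholds.
# Class 1 = levels [0, k], class 2 = [k+1, 255];
# sigma^2(k) = (mG * P1 - m)^2 / (P1 * P2), 0 on degenerate splits.
# Computed from counts so empty-class detection is exact.
bcv_curve <- function(hist) {
  counts <- hist$counts
  n <- hist$n_pixels
  lev <- 0:255
  c1 <- cumsum(counts)
  P1 <- c1 / n
  P2 <- 1 - P1
  m <- cumsum(lev * counts) / n
  mG <- m[256]
  s <- (mG * P1 - m)^2 / (P1 * P2)
  s[c1 == 0L | c1 == n] <- 0
  s
}

#' Between-class variance of a threshold split
#'
#' The Otsu criterion sigma^2(k) = (mG P1 - m)^2 / (P1 P2), where
#' P1 = sum(p_i, i <= k) is the class-1 (background-side) probability,
#' m = sum(i p_i, i <= k) the cumulative mean, and mG the global mean.
#' Degenerate splits with an empty class return 0 so they can never win
#' the maximisation.
#'
#' @param hist A `gray_histogram`.
#' @param k Integer threshold(s) in \[0, 255\] (vectorised).
#' @return Non-negative between-class variance for each `k`.
#' @examples
#' h <- gray_histogram(p = c(0.5, rep(0, 254), 0.5), n_pixels = 2)
#' between_class_variance(h, 127)   # 16256.25
#' @export
between_class_variance <- function(hist, k) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (length(k) < 1L || anyNA(k) || any(k != round(k)) ||
      any(k < 0) || any(k > 255)) {
    stop("`k` must be integer threshold(s) in [0, 255]", call. = FALSE)
  }
  bcv_curve(hist)[as.integer(k) + 1L]
}

#' Exhaustive Otsu threshold
#'
#' Evaluates the between-class variance at every candidate threshold
#' k in \[0, 255\] and returns the maximiser. When a plateau of thresholds
#' attains the maximum (the gray levels between two separated modes), the
#' floor of the mean of the maximising set is returned, centring the
#' threshold between the modes.
#'
#' @param hist A `gray_histogram` with at least two occupied gray levels.
#' @return Integer threshold K in \[0, 255\].
#' @examples
#' img <- gray_image(matrix(c(rep(50L, 100), rep(200L, 100)), 10))
#' otsu_threshold(compute_histogram(img))   # 124
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (sum(hist$counts > 0L) < 2L) {
    stop("degenerate histogram: no threshold separates classes",
         call. = FALSE)
  }
  s <- bcv_curve(hist)
  kmax <- which(s == max(s)) - 1L
  as.integer(floor(mean(kmax)))
}

#' Binarize an image at a threshold
#'
#' Droplet stains are the dark class: a pixel is droplet foreground when
#' f(x, y) < T. The complementary f >= T class is the bright paper
#' background.
#'
#' @param img A [gray_image()].
#' @param threshold Integer T in \[0, 255\].
#' @return A `droplet_mask`: list with logical matrix `pixels` (TRUE =
#'   droplet) and the threshold used.
#' @export
apply_threshold <- function(img, threshold) {
  stopifnot(inherits(img, "gray_image"))
  check_scalar_number(threshold, "threshold", lower = 0, upper = 255,
                      integer = TRUE)
  droplet_mask(img$pixels < threshold, threshold = as.integer(threshold))
}

#' Binary droplet mask
#'
#' @param pixels Logical matrix, TRUE = droplet foreground.
#' @param threshold Optional integer threshold that produced the mask.
#' @return A `droplet_mask` object.
#' @export
droplet_mask <- function(pixels, threshold = NA_integer_) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("mask contains NA", call. = FALSE)
  structure(list(pixels = pixels, threshold = threshold),
            class = "droplet_mask")
}

#' @export
dim.droplet_mask <- function(x) dim(x$pixels)

#' @export
print.droplet_mask <- function(x, ...) {
  cat(sprintf("<droplet_mask> %d x %d px, %d foreground (%.2f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Fixed-threshold segmentation
#'
#' Binarizes at the conventional fixed WSP threshold T = 153
#' (0.60 on the normalized scale); see [fixed_wsp_threshold()].
#'
#' @param img A [gray_image()].
#' @return A `droplet_mask`.
#' @export
fixed_threshold_segment <- function(img) {
  apply_threshold(img, fixed_wsp_threshold())
}
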