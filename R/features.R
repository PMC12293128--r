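# ---- Conventional abundance features (comparators to the RD score) ----

#' Fraction of cells of one type in an image
#'
#' @param image an `image_table`.
#' @param cell_type label.
#' @param denominator `"all"` (default, all cells including cancer) or
#'   `"noncancer"` (non-cancer cells only).
#' @return A fraction in `[0, 1]`; 0 for an absent type.
#' @export
cell_fraction <- function(image, cell_type, denominator = c("all", "noncancer")) {
  assert_image_table(image)
  denominator <- match.arg(denominator)
  pool <- if (denominator == "all") image else
    image[image$compartment == "noncancer", , drop = FALSE]
  if (nrow(pool) == 0L) stop_degenerate("empty denominator pool")
  sum(pool$cell_type == cell_type) / nrow(pool)
}

#' Bounding-box area of an image in square millimetres
#'
#' Default stand-in for the acquisition area when the latter is not recorded.
#'
#' @param image an `image_table`.
#' @return Area in mm^2.
#' @export
image_area <- function(image) {
  assert_image_table(image)
  (diff(range(image$x)) * diff(range(image$y))) / 1e6
}

#' Density of one cell type in cells per square millimetre
#'
#' @inheritParams cell_fraction
#' @param area_mm2 area in mm^2; defaults to the bounding box of all cells
#'   ([image_area()]). Must be positive.
#' @return Cells per mm^2; 0 for an absent type.
#' @export
cell_density <- function(image, cell_type, area_mm2 = NULL) {
  assert_image_table(image)
  area_mm2 <- area_mm2 %||% image_area(image)
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop_config("area_mm2 must be positive")
  sum(image$cell_type == cell_type) / area_mm2
}

#' Relative density of two cell types
#'
#' `density(X) / (density(X) + density(Y))`; the area cancels, so this equals
#' the count ratio. The density-driven counterpart of the RD score.
#'
#' @inheritParams cell_fraction
#' @param x_type,y_type labels.
#' @return A value in `[0, 1]`, or `NA` when both types are absent.
#' @export
relative_density <- function(image, x_type, y_type) {
  assert_image_table(image)
  nx <- sum(image$cell_type == x_type)
  ny <- sum(image$cell_type == y_type)
  if (nx + ny == 0L) return(NA_real_)
  nx / (nx + ny)
}

#' Mean distance of cancer cells to the nearest cell of a type
#'
#' Standalone exposure of [mean_capped_distance()]; the single-type proximity
#' comparator.
#'
#' @inheritParams mean_capped_distance
#' @return Mean capped distance in micrometres.
#' @export
mean_distance_to_cancer <- function(image, cell_type, cap = 500) {
  mean_capped_distance(image, cell_type, cap = cap)
}

#' Long-format feature table for a collection of images
#'
#' Per image and non-cancer type: `fraction:<type>`, `density:<type>`,
#' `mean_dist:<type>`; per canonical pair: `rel_density:<X->Y>`.
#'
#' @param images an `image_table` or list of them.
#' @param types non-cancer types to profile; defaults to all seen.
#' @param cap distance ceiling for `mean_dist` (micrometres).
#' @param area_mm2 optional fixed acquisition area; default bounding box per
#'   image.
#' @param denominator denominator for fractions, see [cell_fraction()].
#' @return Data frame `image_id`, `feature`, `value`. `mean_dist` features
#'   are `NA` for images without cancer cells.
#' @export
feature_table <- function(images, types = NULL, cap = 500, area_mm2 = NULL,
                          denominator = "all") {
  if (inherits(images, "image_table")) images <- list(images)
  if (is.null(types)) {
    types <- sort(unique(unlist(lapply(images, function(im)
      im$cell_type[im$compartment == "noncancer"]))))
  }
  types <- sort(unique(as.character(types)))
  pairs <- if (length(types) >= 2L) canonical_pairs(types) else NULL
  rows <- lapply(images, function(im) {
    id <- im$image_id[[1]]
    has_cancer <- any(im$compartment == "cancer")
    fr <- vapply(types, function(t) cell_fraction(im, t, denominator), numeric(1))
    de <- vapply(types, function(t) cell_density(im, t, area_mm2), numeric(1))
    md <- vapply(types, function(t)
      if (has_cancer) mean_capped_distance(im, t, cap) else NA_real_, numeric(1))
    out <- data.frame(
      image_id = id,
      feature = c(paste0("fraction:", types), paste0("density:", types),
                  paste0("mean_dist:", types)),
      value = c(fr, de, md), stringsAsFactors = FALSE)
    if (!is.null(pairs)) {
      rd <- mapply(function(x, y) relative_density(im, x, y),
                   pairs$x_type, pairs$y_type)
      out <- rbind(out, data.frame(
        image_id = id, feature = paste0("rel_density:", pairs$pair),
        value = unname(rd), stringsAsFactors = FALSE))
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
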