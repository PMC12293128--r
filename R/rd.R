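# ---- RD scores: capped nearest distances and relative-distance statistic ----

ref_rows <- function(image, reference_types = NULL) {
  if (is.null(reference_types)) image$compartment == "cancer"
  else image$cell_type %in% reference_types
}

#' Capped nearest distance from each cancer cell to a target cell type
#'
#' For every reference cell (by default every cancer cell) in the image,
#' returns the Euclidean distance in micrometres to the nearest cell of
#' `target_type`. Distances above `cap`, or an absent target type, yield
#' exactly `cap`: beyond ~500 um two cells are past typical cytokine
#' diffusion ranges, so larger separations are treated as equally "out of
#' reach".
#'
#' @param image an `image_table`.
#' @param target_type a single cell-type label.
#' @param cap distance ceiling in micrometres (default 500).
#' @param reference_types optional labels to use as the reference ("cancer")
#'   compartment instead of `compartment == "cancer"`.
#' @return Numeric vector, one distance per reference cell, all in `(0, cap]`
#'   (0 only for coincident coordinates).
#' @export
nearest_distance_per_cancer_cell <- function(image, target_type, cap = 500,
                                             reference_types = NULL) {
  assert_image_table(image)
  if (!is.numeric(cap) || cap <= 0) stop_config("cap must be a positive distance")
  ref <- image[ref_rows(image, reference_types), , drop = FALSE]
  if (nrow(ref) == 0L)
    stop_degenerate(paste0("image ", image$image_id[[1]],
                           " has no reference (cancer) cells"))
  tgt <- image[image$cell_type == target_type, , drop = FALSE]
  .nn_capped_cpp(ref$x, ref$y, tgt$x, tgt$y, cap)
}

#' Mean capped distance from cancer cells to a cell type
#'
#' Arithmetic mean of [nearest_distance_per_cancer_cell()]; the d-bar entering
#' the RD score.
#'
#' @inheritParams nearest_distance_per_cancer_cell
#' @return A scalar in `(0, cap]` micrometres.
#' @export
mean_capped_distance <- function(image, target_type, cap = 500,
                                 reference_types = NULL) {
  mean(nearest_distance_per_cancer_cell(image, target_type, cap, reference_types))
}

#' Relative-distance (RD) score of a directional cell-type pair
#'
#' `RD(X -> Y) = dbar_x / (dbar_x + dbar_y)` where `dbar` is the mean capped
#' nearest distance from cancer cells to each type. Values above 0.5 mean
#' cancer cells sit farther from X than from Y. By construction
#' `RD(X -> Y) + RD(Y -> X) = 1`.
#'
#' @param dbar_x,dbar_y mean capped distances in micrometres (vectorised).
#' @return RD scores in `(0, 1)`.
#' @export
rd_score <- function(dbar_x, dbar_y) {
  if (any(dbar_x < 0) || any(dbar_y < 0))
    stop_config("mean capped distances must be non-negative")
  if (any(dbar_x + dbar_y == 0))
    stop_degenerate("both mean distances are zero; RD is undefined")
  dbar_x / (dbar_x + dbar_y)
}

#' Canonical unordered pairs of cell types
#'
#' One direction per unordered pair (lexicographically smaller label first);
#' the reverse direction is the complement `1 - RD` and is never stored.
#'
#' @param types character vector of at least two distinct labels.
#' @return Data frame with columns `x_type`, `y_type`, `pair` (`"X->Y"`).
#' @export
canonical_pairs <- function(types) {
  types <- sort(unique(as.character(types)))
  if (length(types) < 2L)
    stop_config("need at least two cell types to form pairs")
  cmb <- combn(types, 2L)
  data.frame(x_type = cmb[1L, ], y_type = cmb[2L, ],
             pair = paste0(cmb[1L, ], "->", cmb[2L, ]),
             stringsAsFactors = FALSE)
}

new_rd_score_set <- function(scores, dbar, cap, reference) {
  structure(list(scores = scores, dbar = dbar, cap = cap,
                 reference = reference),
            class = "rd_score_set")
}

#' @export
print.rd_score_set <- function(x, ...) {
  cat("RD score set (reference: ", x$reference, ", cap ", x$cap, " um)\n",
      sep = "")
  cat("  ", length(unique(x$scores$image_id)), " image(s) x ",
      length(unique(x$scores$pair)), " pair(s)\n", sep = "")
  invisible(x)
}

#' RD scores for all canonical cell-type pairs across images
#'
#' For every image with at least one reference (cancer) cell, computes the
#' mean capped nearest distance from the reference cells to each non-cancer
#' type and the RD score of every canonical pair. Images without reference
#' cells are skipped with one warning naming them: RD is undefined there.
#' Pairs whose both types are absent get `dbar = cap` on both sides and
#' hence RD = 0.5, the no-information value; the matrix stays dense.
#'
#' @param images an `image_table` or (named) list of them.
#' @param noncancer_types the pair universe; defaults to all non-cancer types
#'   seen across the images. Needs at least two labels.
#' @param cap distance ceiling in micrometres.
#' @param reference_types optional labels used as the reference compartment
#'   (see [nearest_distance_per_cancer_cell()]).
#' @param reference_label name recorded for the reference ("cancer" default).
#' @return An `rd_score_set`: `$scores` (image_id, x_type, y_type, pair, rd),
#'   `$dbar` (image_id, cell_type, dbar), `$cap`, `$reference`.
#' @export
rd_matrix <- function(images, noncancer_types = NULL, cap = 500,
                      reference_types = NULL,
                      reference_label = if (is.null(reference_types)) "cancer"
                                        else paste(reference_types, collapse = "+")) {
  if (inherits(images, "image_table")) images <- list(images)
  if (length(images) == 0L) stop_config("no images supplied")
  lapply(images, assert_image_table)
  if (is.null(noncancer_types)) {
    noncancer_types <- sort(unique(unlist(lapply(images, function(im)
      im$cell_type[im$compartment == "noncancer"]))))
  }
  noncancer_types <- sort(unique(as.character(noncancer_types)))
  if (length(noncancer_types) < 2L)
    stop_config("need at least two non-cancer types to form pairs")
  pairs <- canonical_pairs(noncancer_types)

  score_rows <- vector("list", length(images))
  dbar_rows <- vector("list", length(images))
  skipped <- character(0)
  for (i in seq_along(images)) {
    im <- images[[i]]
    id <- im$image_id[[1]]
    if (!any(ref_rows(im, reference_types))) {
      skipped <- c(skipped, id)
      next
    }
    db <- vapply(noncancer_types, function(t)
      mean_capped_distance(im, t, cap = cap, reference_types = reference_types),
      numeric(1))
    rd <- rd_score(db[pairs$x_type], db[pairs$y_type])
    score_rows[[i]] <- data.frame(image_id = id, x_type = pairs$x_type,
                                  y_type = pairs$y_type, pair = pairs$pair,
                                  rd = unname(rd), stringsAsFactors = FALSE)
    dbar_rows[[i]] <- data.frame(image_id = id, cell_type = noncancer_types,
                                 dbar = unname(db), stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " image(s) with no reference cells: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  scores <- do.call(rbind, score_rows[!vapply(score_rows, is.null, TRUE)])
  dbar <- do.call(rbind, dbar_rows[!vapply(dbar_rows, is.null, TRUE)])
  if (is.null(scores)) {
    scores <- data.frame(image_id = character(0), x_type = character(0),
                         y_type = character(0), pair = character(0),
                         rd = numeric(0), stringsAsFactors = FALSE)
    dbar <- data.frame(image_id = character(0), cell_type = character(0),
                       dbar = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(scores) <- NULL; rownames(dbar) <- NULL
  new_rd_score_set(scores, dbar, cap, reference_label)
}

#' RD scores relative to specific cancer subtypes
#'
#' Recomputes the RD matrix once per reference: each declared cancer subtype
#' plays the "cancer cell" role in turn, optionally preceded by the aggregate
#' of all cancer cells. Pair members are always the non-cancer (TME) types;
#' images lacking a given reference subtype are skipped for that reference
#' only.
#'
#' @param images list of `image_table` objects.
#' @param tme_types the non-cancer pair universe (>= 2 labels).
#' @param reference_types cancer subtype labels to use as references; must be
#'   a subset of the labels carrying `compartment == "cancer"`.
#' @param include_aggregate also compute scores against all cancer cells
#'   pooled (reference name `"all_cancer"`). Default `TRUE`.
#' @param cap distance ceiling in micrometres.
#' @return Named list of `rd_score_set` objects, one per reference.
#' @export
rd_matrix_by_reference <- function(images, tme_types, reference_types,
                                   include_aggregate = TRUE, cap = 500) {
  if (inherits(images, "image_table")) images <- list(images)
  if (length(reference_types) == 0L && !include_aggregate)
    stop_config("empty reference set with include_aggregate = FALSE")
  cancer_labels <- unique(unlist(lapply(images, function(im)
    im$cell_type[im$compartment == "cancer"])))
  missing_ref <- setdiff(reference_types, cancer_labels)
  if (length(missing_ref))
    stop_config(paste0("reference type(s) not in the cancer compartment: ",
                       paste(missing_ref, collapse = ", ")))
  out <- list()
  if (include_aggregate) {
    out[["all_cancer"]] <- rd_matrix(images, noncancer_types = tme_types,
                                     cap = cap, reference_types = NULL,
                                     reference_label = "all_cancer")
  }
  for (ref in reference_types) {
    out[[ref]] <- suppressWarnings(
      rd_matrix(images, noncancer_types = tme_types, cap = cap,
                reference_types = ref, reference_label = ref))
  }
  out
}
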