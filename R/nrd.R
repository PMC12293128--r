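# ---- Permutation null and normalized RD (NRD) scores ----

#' Shuffle non-cancer cell-type labels over their fixed positions
#'
#' One draw from the permutation null: cancer cells are untouched and the
#' multiset of non-cancer labels is randomly reassigned to the observed
#' non-cancer positions, so per-type counts (hence densities) and the spatial
#' support are preserved exactly. This is the null that the NRD normalization
#' controls for: any remaining signal cannot be explained by how many cells
#' of each type there are.
#'
#' @param image an `image_table` with at least two non-cancer cells.
#' @return An `image_table` with permuted non-cancer labels.
#' @export
permute_labels <- function(image) {
  assert_image_table(image)
  idx <- which(image$compartment == "noncancer")
  if (length(idx) < 2L)
    stop_degenerate(paste0("image ", image$image_id[[1]],
                           " has fewer than two non-cancer cells"))
  image$cell_type[idx] <- sample(image$cell_type[idx])
  image
}

#' Permutation null distribution of RD scores for one image
#'
#' Draws `n_perm` label permutations (shared across pairs: each shuffle
#' scores every pair) and returns the mean and standard deviation of the
#' permuted RD scores per pair. Distances reuse the same cap as the observed
#' statistic. Deterministic given the RNG state (`set.seed()` or `seed`).
#'
#' @param image an `image_table` with reference cells and >= 2 non-cancer
#'   cells.
#' @param types the non-cancer pair universe; defaults to all non-cancer
#'   types in the image.
#' @param n_perm number of permutations (default 1000).
#' @param cap distance ceiling in micrometres.
#' @param reference_types optional reference compartment labels (see
#'   [rd_matrix()]).
#' @param seed optional integer seed set before drawing.
#' @return Data frame with columns `image_id`, `x_type`, `y_type`, `pair`,
#'   `mean_null`, `sd_null`, `n_perm`. `sd_null` is the sample standard
#'   deviation (0 when `n_perm = 1`).
#' @export
null_distribution <- function(image, types = NULL, n_perm = 1000, cap = 500,
                              reference_types = NULL, seed = NULL) {
  assert_image_table(image)
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1L) stop_config("n_perm must be at least 1")
  ref <- image[ref_rows(image, reference_types), , drop = FALSE]
  if (nrow(ref) == 0L)
    stop_degenerate(paste0("image ", image$image_id[[1]],
                           " has no reference (cancer) cells"))
  nc <- image[image$compartment == "noncancer", , drop = FALSE]
  if (nrow(nc) < 2L)
    stop_degenerate(paste0("image ", image$image_id[[1]],
                           " has fewer than two non-cancer cells"))
  if (is.null(types)) types <- sort(unique(nc$cell_type))
  types <- sort(unique(as.character(types)))
  pairs <- canonical_pairs(types)

  # capped cross-distance matrix reference x non-cancer; label shuffles
  # re-partition its columns, so it is computed once
  D <- sqrt(outer(ref$x, nc$x, "-")^2 + outer(ref$y, nc$y, "-")^2)
  D <- pmin(D, cap)
  code <- match(nc$cell_type, types)          # NA = outside the universe
  code[is.na(code)] <- length(types) + 1L     # shuffled but never scored
  res <- .rd_null_perm_cpp(D, as.integer(code), length(types),
                           match(pairs$x_type, types),
                           match(pairs$y_type, types),
                           as.integer(n_perm), cap)
  data.frame(image_id = image$image_id[[1]],
             x_type = pairs$x_type, y_type = pairs$y_type, pair = pairs$pair,
             mean_null = res$mean_null, sd_null = res$sd_null,
             n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
}

#' Normalize RD scores against their permutation null
#'
#' `NRD = (RD - mean(RD')) / sd(RD')`, the z-score of the observed RD within
#' the permutation null. `NA` where `sd(RD') = 0`: a degenerate null carries
#' no normalizing information.
#'
#' @param rd an `rd_score_set` from [rd_matrix()].
#' @param null a null summary from [null_distribution()] (rows for every
#'   scored image/pair).
#' @return Data frame `image_id`, `x_type`, `y_type`, `pair`, `rd`,
#'   `mean_null`, `sd_null`, `nrd`.
#' @export
nrd_score <- function(rd, null) {
  if (!inherits(rd, "rd_score_set")) stop_schema("rd must be an rd_score_set")
  obs <- rd$scores
  key_obs <- paste(obs$image_id, obs$pair, sep = "\r")
  key_null <- paste(null$image_id, null$pair, sep = "\r")
  miss <- setdiff(key_obs, key_null)
  if (length(miss))
    stop_alignment(paste0("null summary missing ", length(miss),
                          " (image, pair) key(s), e.g. ",
                          paste(head(gsub("\r", " / ", miss), 3), collapse = "; ")))
  idx <- match(key_obs, key_null)
  out <- obs
  out$mean_null <- null$mean_null[idx]
  out$sd_null <- null$sd_null[idx]
  out$nrd <- ifelse(out$sd_null == 0, NA_real_,
                    (out$rd - out$mean_null) / out$sd_null)
  out
}

#' RD and NRD scores for a collection of images
#'
#' Convenience wrapper: [rd_matrix()] plus a per-image [null_distribution()]
#' and [nrd_score()]. Images without reference cells, or with fewer than two
#' non-cancer cells, are skipped with a warning.
#'
#' @inheritParams rd_matrix
#' @param n_perm permutations per image (default 1000).
#' @param seed optional integer seed (set once, before all images).
#' @return Data frame as returned by [nrd_score()].
#' @export
nrd_matrix <- function(images, noncancer_types = NULL, cap = 500,
                       n_perm = 1000, reference_types = NULL, seed = NULL) {
  if (inherits(images, "image_table")) images <- list(images)
  if (!is.null(seed)) set.seed(seed)
  rd <- rd_matrix(images, noncancer_types = noncancer_types, cap = cap,
                  reference_types = reference_types)
  types <- sort(unique(c(rd$scores$x_type, rd$scores$y_type)))
  ok_ids <- unique(rd$scores$image_id)
  nulls <- list(); degenerate <- character(0)
  for (im in images) {
    id <- im$image_id[[1]]
    if (!id %in% ok_ids) next
    res <- tryCatch(
      null_distribution(im, types = types, n_perm = n_perm, cap = cap,
                        reference_types = reference_types),
      proxiscore_degenerate_error = function(e) NULL)
    if (is.null(res)) degenerate <- c(degenerate, id) else nulls[[id]] <- res
  }
  if (length(degenerate)) {
    warning("skipped ", length(degenerate),
            " image(s) with a degenerate permutation null: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    rd$scores <- rd$scores[!rd$scores$image_id %in% degenerate, , drop = FALSE]
  }
  nrd_score(rd, do.call(rbind, nulls))
}
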