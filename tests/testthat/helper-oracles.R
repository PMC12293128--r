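# independent oracles, deliberately naive

# O(n^2) capped nearest-neighbour scan
brute_nn_capped <- function(qx, qy, tx, ty, cap) {
  if (length(tx) == 0L) return(rep(cap, length(qx)))
  vapply(seq_along(qx), function(i) {
    d <- sqrt((qx[i] - tx)^2 + (qy[i] - ty)^2)
    min(min(d), cap)
  }, numeric(1))
}

# RD of one pair from scratch (brute force), NA when no cancer cells
brute_rd <- function(image, x_type, y_type, cap = 500) {
  ref <- image[image$compartment == "cancer", , drop = FALSE]
  if (nrow(ref) == 0L) return(NA_real_)
  db <- function(t) {
    tg <- image[image$cell_type == t, , drop = FALSE]
    mean(brute_nn_capped(ref$x, ref$y, tg$x, tg$y, cap))
  }
  dx <- db(x_type); dy <- db(y_type)
  dx / (dx + dy)
}

# exact permutation distribution of RD for a tiny image: enumerate every
# assignment of the non-cancer label multiset to the fixed positions
enumerate_null_rd <- function(image, x_type, y_type, cap = 500) {
  nc_idx <- which(image$compartment == "noncancer")
  labs <- image$cell_type[nc_idx]
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  vapply(perms(labs), function(lab) {
    im <- image
    im$cell_type[nc_idx] <- lab
    brute_rd(im, x_type, y_type, cap)
  }, numeric(1))
}
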