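test_that("nearest capped distances match hand arithmetic and the cap rule", {
  im <- toy_image(x = c(0, 3, 10), y = c(0, 4, 0),
                  cell_type = c("Cancer", "X", "X"))
  expect_equal(nearest_distance_per_cancer_cell(im, "X", cap = 500), 5)
  # absent type: exactly the cap
  expect_equal(nearest_distance_per_cancer_cell(im, "Y", cap = 500), 500)
  # a cell beyond the cap contributes exactly the cap
  far <- toy_image(x = c(0, 600), y = c(0, 0),
                   cell_type = c("Cancer", "X"))
  expect_identical(nearest_distance_per_cancer_cell(far, "X", cap = 500), 500)
  # no cancer cells: undefined
  nc <- toy_image(x = c(0, 1), y = c(0, 1), cell_type = c("X", "Y"))
  expect_error(nearest_distance_per_cancer_cell(nc, "X"),
               class = "proxiscore_degenerate_error")
})

test_that("mean capped distance averages per-cancer-cell distances", {
  im <- toy_image(x = c(0, 20, 5, 35), y = c(0, 0, 0, 0),
                  cell_type = c("Cancer", "Cancer", "X", "X"))
  # distances 5 and 15
  expect_equal(mean_capped_distance(im, "X"), 10)
  expect_equal(mean_capped_distance(im, "Y"), 500)
})

test_that("the RD formula and its complement behave as specified", {
  expect_equal(rd_score(100, 100), 0.5)
  expect_equal(rd_score(500, 100), 500 / 600)
  expect_equal(rd_score(100, 500), 1 - 500 / 600)
  expect_error(rd_score(0, 0), class = "proxiscore_degenerate_error")
})

test_that("canonical pair enumeration gives n(n-1)/2 pairs, one direction", {
  p15 <- canonical_pairs(paste0("t", sprintf("%02d", 1:15)))
  expect_equal(nrow(p15), 105L)
  p20 <- canonical_pairs(paste0("t", sprintf("%02d", 1:20)))
  expect_equal(nrow(p20), 190L)
  expect_true(all(p15$x_type < p15$y_type))
  expect_error(canonical_pairs("only_one"), class = "proxiscore_config_error")
})

test_that("rd_matrix scores every pair per image and skips cancer-free images", {
  set.seed(7)
  imgs <- csr_images(4, c(Cancer = 25, A = 20, B = 20, C = 20))
  # strip cancer cells from one image
  imgs$img002 <- imgs$img002[imgs$img002$compartment != "cancer", ]
  class(imgs$img002) <- c("image_table", "data.frame")
  expect_warning(rd <- rd_matrix(imgs), "img002")
  expect_setequal(unique(rd$scores$image_id), c("img001", "img003", "img004"))
  expect_equal(nrow(rd$scores), 3 * 3)       # 3 images x C(3,2) pairs
  expect_true(all(rd$scores$rd > 0 & rd$scores$rd < 1))
  expect_error(rd_matrix(imgs, noncancer_types = "A"),
               class = "proxiscore_config_error")
})

test_that("rd_matrix agrees with a from-scratch brute-force computation", {
  set.seed(11)
  imgs <- csr_images(5, c(Cancer = 15, A = 12, B = 9))
  rd <- rd_matrix(imgs)
  for (i in seq_len(nrow(rd$scores))) {
    row <- rd$scores[i, ]
    expect_equal(row$rd,
                 brute_rd(imgs[[row$image_id]], row$x_type, row$y_type),
                 tolerance = 1e-12)
  }
})

test_that("grid-accelerated distances equal the O(n^2) oracle exactly", {
  set.seed(23)
  for (rep in 1:25) {
    im <- random_image(max_cells = 400)
    ref <- im[im$compartment == "cancer", ]
    if (nrow(ref) == 0) next
    for (t in c("A", "B")) {
      tg <- im[im$cell_type == t, ]
      got <- nearest_distance_per_cancer_cell(im, t, cap = 500)
      expect_identical(got, brute_nn_capped(ref$x, ref$y, tg$x, tg$y, 500))
    }
  }
})

test_that("complement identity holds to 1e-12 on simulated images", {
  set.seed(31)
  imgs <- csr_images(20, c(Cancer = 20, A = 15, B = 10, C = 25))
  rd <- rd_matrix(imgs)
  db <- rd$dbar
  for (i in seq_len(nrow(rd$scores))) {
    row <- rd$scores[i, ]
    dy <- db$dbar[db$image_id == row$image_id & db$cell_type == row$y_type]
    dx <- db$dbar[db$image_id == row$image_id & db$cell_type == row$x_type]
    expect_equal(row$rd + rd_score(dy, dx), 1, tolerance = 1e-12)
  }
})

test_that("raising the cap never decreases a mean distance", {
  set.seed(37)
  imgs <- csr_images(10, c(Cancer = 15, A = 3, B = 2), field = 900)
  for (im in imgs) {
    for (t in c("A", "B")) {
      expect_lte(mean_capped_distance(im, t, cap = 300),
                 mean_capped_distance(im, t, cap = 500))
    }
  }
})

test_that("RD is invariant to coordinate scaling below the cap", {
  set.seed(41)
  im <- csr_image(c(Cancer = 20, A = 15, B = 15), field = 200)
  scaled <- im
  scaled$x <- im$x * 0.5
  scaled$y <- im$y * 0.5
  class(scaled) <- class(im)
  for (t in c("A", "B")) {
    expect_equal(mean_capped_distance(scaled, t),
                 0.5 * mean_capped_distance(im, t), tolerance = 1e-12)
  }
  expect_equal(rd_matrix(list(im))$scores$rd,
               rd_matrix(list(scaled))$scores$rd, tolerance = 1e-12)
})

test_that("subtype references score TME pairs against each reference", {
  set.seed(43)
  n <- 120
  im <- image_table(
    x = runif(n, 0, 500), y = runif(n, 0, 500),
    cell_type = sample(c("CanA", "CanB", "T1", "T2", "T3"), n, replace = TRUE),
    cancer_types = c("CanA", "CanB"), image_id = "im1")
  sets <- rd_matrix_by_reference(list(im1 = im), tme_types = c("T1", "T2", "T3"),
                                 reference_types = c("CanA", "CanB"))
  expect_named(sets, c("all_cancer", "CanA", "CanB"))
  expect_true(all(vapply(sets, function(s) nrow(s$scores), 1L) == 3L))

  # the reference cells are the query points, so the aggregate mean distance
  # is the cell-count-weighted mean of the subtype means (a convex
  # combination: min <= aggregate <= max)
  n_a <- sum(im$cell_type == "CanA")
  n_b <- sum(im$cell_type == "CanB")
  agg <- sets$all_cancer$dbar
  for (t in c("T1", "T2", "T3")) {
    d_agg <- agg$dbar[agg$cell_type == t]
    d_a <- sets$CanA$dbar$dbar[sets$CanA$dbar$cell_type == t]
    d_b <- sets$CanB$dbar$dbar[sets$CanB$dbar$cell_type == t]
    expect_equal(d_agg, (n_a * d_a + n_b * d_b) / (n_a + n_b),
                 tolerance = 1e-12)
    expect_gte(d_agg, min(d_a, d_b) - 1e-12)
    expect_lte(d_agg, max(d_a, d_b) + 1e-12)
  }

  # a reference subtype absent from an image drops that image, for that
  # reference only
  im2 <- image_table(x = runif(40, 0, 500), y = runif(40, 0, 500),
                     cell_type = sample(c("CanA", "T1", "T2"), 40, TRUE),
                     cancer_types = c("CanA", "CanB"), image_id = "im2")
  sets2 <- rd_matrix_by_reference(list(im1 = im, im2 = im2),
                                  tme_types = c("T1", "T2"),
                                  reference_types = c("CanA", "CanB"))
  expect_setequal(unique(sets2$CanA$scores$image_id), c("im1", "im2"))
  expect_setequal(unique(sets2$CanB$scores$image_id), "im1")

  expect_error(rd_matrix_by_reference(list(im1 = im), tme_types = c("T1", "T2"),
                                      reference_types = "NotCancer"),
               "NotCancer", class = "proxiscore_config_error")
  expect_error(rd_matrix_by_reference(list(im1 = im), tme_types = c("T1", "T2"),
                                      reference_types = character(0),
                                      include_aggregate = FALSE),
               class = "proxiscore_config_error")
})
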