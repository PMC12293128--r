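# in-code fixtures: small images built directly from coordinates

toy_image <- function(x, y, cell_type, cancer_types = "Cancer", id = "img1") {
  image_table(x = x, y = y, cell_type = cell_type,
              cancer_types = cancer_types, image_id = id)
}

# completely spatially random image with exact per-type counts
csr_image <- function(counts, field = 600, id = "img1",
                      cancer_types = "Cancer") {
  n <- sum(counts)
  image_table(x = runif(n, 0, field), y = runif(n, 0, field),
              cell_type = rep(names(counts), counts),
              cancer_types = cancer_types, image_id = id)
}

csr_images <- function(n_images, counts, field = 600, prefix = "img") {
  out <- lapply(seq_len(n_images), function(i)
    csr_image(counts, field = field, id = sprintf("%s%03d", prefix, i)))
  names(out) <- vapply(out, function(im) im$image_id[[1]], "")
  out
}

# random image with Poisson counts per type, for oracle sweeps
random_image <- function(max_cells = 500, field = 800, id = "img1",
                         types = c("Cancer", "A", "B", "C")) {
  n <- sample(seq(10, max_cells), 1)
  image_table(x = runif(n, 0, field), y = runif(n, 0, field),
              cell_type = sample(types, n, replace = TRUE),
              cancer_types = "Cancer", image_id = id)
}
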