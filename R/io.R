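#' Construct an image table
#'
#' An `image_table` holds all cells of one acquisition: positions in
#' micrometres, a cell-type label per cell, and a `compartment` flag telling
#' cancer (reference) cells apart from the non-cancer milieu. It is an
#' ordinary data frame with columns `image_id`, `sample_id`, `patient_id`,
#' `x`, `y`, `cell_type`, `compartment`.
#'
#' @param x,y numeric coordinates in micrometres (finite, non-negative).
#' @param cell_type character vector of cell-type labels.
#' @param cancer_types character vector of labels that form the cancer
#'   compartment; every other label is a non-cancer type.
#' @param image_id,sample_id,patient_id identifiers; `sample_id` and
#'   `patient_id` default to `image_id`.
#' @return A data frame of class `image_table`.
#' @export
image_table <- function(x, y, cell_type, cancer_types,
                        image_id = "img1", sample_id = image_id,
                        patient_id = image_id) {
  if (length(x) != length(y) || length(x) != length(cell_type))
    stop_schema("x, y and cell_type must have equal length")
  if (length(x) == 0L)
    stop_schema("an image table needs at least one cell")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_schema("coordinates must be finite")
  if (any(x < 0) || any(y < 0))
    stop_schema("coordinates must be non-negative")
  if (length(cancer_types) == 0L)
    stop_config("cancer_types must be non-empty")
  df <- data.frame(
    image_id = as.character(image_id),
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    x = as.numeric(x), y = as.numeric(y),
    cell_type = as.character(cell_type),
    compartment = ifelse(cell_type %in% cancer_types, "cancer", "noncancer"),
    stringsAsFactors = FALSE
  )
  class(df) <- c("image_table", "data.frame")
  df
}

assert_image_table <- function(image) {
  if (!inherits(image, "image_table"))
    stop_schema("expected an image_table (see image_table() or read_cell_table())")
  invisible(image)
}

#' Split a combined cell data frame into image tables
#'
#' @param df data frame with columns `image_id`, `x`, `y`, `cell_type` and
#'   optionally `sample_id`, `patient_id`.
#' @param cancer_types labels forming the cancer compartment.
#' @param pixel_to_um positive scale multiplying the raw coordinates; 1 when
#'   the input is already in micrometres.
#' @return Named list of `image_table` objects, one per distinct `image_id`.
#' @export
as_image_tables <- function(df, cancer_types, pixel_to_um = 1) {
  if (!is.numeric(pixel_to_um) || pixel_to_um <= 0)
    stop_config("pixel_to_um must be a positive scalar")
  for (col in c("image_id", "x", "y", "cell_type"))
    if (!col %in% names(df)) stop_schema(paste0("missing required column: ", col))
  ids <- as.character(df$image_id)
  out <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    sub <- df[idx, , drop = FALSE]
    image_table(
      x = sub$x * pixel_to_um, y = sub$y * pixel_to_um,
      cell_type = sub$cell_type, cancer_types = cancer_types,
      image_id = sub$image_id[[1]],
      sample_id = if ("sample_id" %in% names(sub)) sub$sample_id[[1]] else sub$image_id[[1]],
      patient_id = if ("patient_id" %in% names(sub)) sub$patient_id[[1]] else sub$image_id[[1]]
    )
  })
  out[unique(ids)]
}

#' Read a per-cell table from delimited text
#'
#' Expects a header with columns `image_id`, `x_um`, `y_um`, `cell_type`
#' (plus optional `sample_id`, `patient_id`); one row per cell. Any label not
#' in `cancer_types` is retained as its own non-cancer type, so no cell-type
#' vocabulary needs declaring up front. Labels outside `known_types` (when
#' given) are reported via [message()].
#'
#' @param path file path.
#' @param cancer_types labels forming the cancer compartment (non-empty).
#' @param pixel_to_um positive scale applied to coordinates (default 1:
#'   input already in micrometres).
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @param known_types optional vector of expected labels, for logging only.
#' @return Named list of `image_table` objects (see [as_image_tables()]).
#' @export
read_cell_table <- function(path, cancer_types, pixel_to_um = 1,
                            delim = ",", known_types = NULL) {
  if (length(cancer_types) == 0L) stop_config("cancer_types must be non-empty")
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_schema(paste0("cell table not found: ", path))
  raw <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                  colClasses = "character")
  for (col in c("image_id", "x_um", "y_um", "cell_type"))
    if (!col %in% names(raw)) stop_schema(paste0("missing required column: ", col))
  x <- suppressWarnings(as.numeric(raw$x_um))
  y <- suppressWarnings(as.numeric(raw$y_um))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop_parse(paste0("non-numeric coordinate in row(s): ",
                      paste(head(bad, 5), collapse = ", ")))
  df <- data.frame(
    image_id = raw$image_id,
    sample_id = raw[["sample_id"]] %||% raw$image_id,
    patient_id = raw[["patient_id"]] %||% raw$image_id,
    x = x, y = y, cell_type = raw$cell_type,
    stringsAsFactors = FALSE
  )
  if (!is.null(known_types)) {
    unknown <- setdiff(unique(df$cell_type), c(known_types, cancer_types))
    if (length(unknown))
      message("retaining unexpected non-cancer cell type(s): ",
              paste(unknown, collapse = ", "))
  }
  as_image_tables(df, cancer_types = cancer_types, pixel_to_um = pixel_to_um)
}

#' Read a per-patient clinical table
#'
#' Delimited text keyed by `patient_id`, with optional survival
#' (`os_time` in months, `os_event` 0/1), covariates (`age`, `sex`, `bmi`,
#' `smoking`, `stage`, `histology`), treatment `arm`
#' (chemo/immunochemo/none), binary `response` (pCR/RD) and sampling
#' `timepoint`. Unparseable numeric fields become `NA`, never 0. A missing
#' `arm` column yields `arm = "none"` and `response = NA`.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return Data frame of class `clinical_table`, one row per patient.
#' @export
read_clinical_table <- function(path, delim = ",") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_schema(paste0("clinical table not found: ", path))
  raw <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!"patient_id" %in% names(raw))
    stop_schema("missing required column: patient_id")
  dup <- unique(raw$patient_id[duplicated(raw$patient_id)])
  if (length(dup))
    stop_integrity(paste0("duplicated patient_id: ", paste(dup, collapse = ", ")))
  num <- function(col) {
    if (is.null(raw[[col]])) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  chr <- function(col, default = NA_character_) {
    v <- raw[[col]] %||% rep(default, nrow(raw))
    v[!nzchar(v)] <- NA_character_
    v
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    os_time = num("os_time"), os_event = num("os_event"),
    age = num("age"), sex = chr("sex"), bmi = num("bmi"),
    smoking = chr("smoking"), stage = chr("stage"),
    histology = chr("histology"),
    arm = chr("arm", default = "none"),
    response = chr("response"),
    timepoint = chr("timepoint"),
    stringsAsFactors = FALSE
  )
  out$arm[is.na(out$arm)] <- "none"
  out$response[out$arm == "none"] <- NA_character_
  bad_t <- which(!is.na(out$os_event) & !is.na(out$os_time) & out$os_time <= 0)
  if (length(bad_t))
    stop_integrity(paste0("non-positive os_time for patient(s): ",
                          paste(out$patient_id[bad_t], collapse = ", ")))
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write scores to long-format delimited text
#'
#' Serialises an [rd_matrix()] result (or any long data frame with columns
#' `image_id`, `pair`, and one score column) as
#' `image_id,pair,score`; directional pairs are written `"X->Y"`. Values
#' round-trip through [read_scores()] to within 1e-12.
#'
#' @param scores an `rd_score_set`, or a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "rd_score_set")) {
    df <- data.frame(image_id = scores$scores$image_id,
                     pair = scores$scores$pair,
                     score = scores$scores$rd,
                     stringsAsFactors = FALSE)
  } else if (is.data.frame(scores)) {
    score_col <- first_col(scores, c("score", "nrd", "rd", "value"))
    if (is.null(score_col) || !all(c("image_id", "pair") %in% names(scores)))
      stop_schema("data frame must have columns image_id, pair and a score column")
    df <- data.frame(image_id = scores$image_id, pair = scores$pair,
                     score = scores[[score_col]], stringsAsFactors = FALSE)
  } else {
    stop_schema("scores must be an rd_score_set or a data frame")
  }
  if (nrow(df) == 0L) stop_schema("refusing to write an empty score set")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format score table written by [write_scores()]
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return Data frame with columns `image_id`, `pair`, `score`, plus the
#'   pair split into `x_type`, `y_type`.
#' @export
read_scores <- function(path, delim = ",") {
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE)
  for (col in c("image_id", "pair", "score"))
    if (!col %in% names(df)) stop_schema(paste0("missing required column: ", col))
  parts <- strsplit(df$pair, "->", fixed = TRUE)
  df$x_type <- vapply(parts, `[`, "", 1L)
  df$y_type <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, "")
  df
}
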