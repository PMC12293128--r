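# ---- End-to-end workflows: survival (LUAD-style) and response (TNBC-style) ----

#' Workflow configuration
#'
#' Bundles inputs and tuning parameters for [run_survival_workflow()] and
#' [run_response_workflow()]. Defaults: 500 um distance cap, 1000
#' permutations, FDR threshold 0.05, mean aggregation of replicate images.
#'
#' @param cells path to a cell CSV (see [read_cell_table()]) or a list of
#'   `image_table` objects.
#' @param clinical path to a clinical CSV (see [read_clinical_table()]) or a
#'   `clinical_table`.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param cancer_types labels forming the cancer compartment (needed when
#'   `cells` is a path).
#' @param cap,n_perm,fdr,seed tuning parameters.
#' @param aggregate `"mean"` or `"per_image"` patient aggregation policy.
#' @param adjust optional covariates for adjusted Cox models.
#' @param arm,timepoint filters for the response workflow.
#' @param tme_types,reference_types,include_aggregate response-workflow pair
#'   universe and cancer-subtype references (defaults: all non-cancer types;
#'   aggregate reference only).
#' @param pixel_to_um coordinate scale for file input.
#' @return List of class `run_config`.
#' @export
run_config <- function(cells, clinical, out_dir = NULL, cancer_types = NULL,
                       cap = 500, n_perm = 1000, fdr = 0.05, seed = 1,
                       aggregate = "mean", adjust = NULL,
                       arm = NULL, timepoint = "baseline",
                       tme_types = NULL, reference_types = character(0),
                       include_aggregate = TRUE, pixel_to_um = 1) {
  structure(list(cells = cells, clinical = clinical, out_dir = out_dir,
                 cancer_types = cancer_types, cap = cap, n_perm = n_perm,
                 fdr = fdr, seed = seed, aggregate = aggregate,
                 adjust = adjust, arm = arm, timepoint = timepoint,
                 tme_types = tme_types, reference_types = reference_types,
                 include_aggregate = include_aggregate,
                 pixel_to_um = pixel_to_um),
            class = "run_config")
}

load_inputs <- function(config) {
  cells <- config$cells
  if (is.character(cells)) {
    if (!file.exists(cells)) stop_schema(paste0("cell table not found: ", cells))
    if (is.null(config$cancer_types))
      stop_config("cancer_types is required when cells is a file path")
    cells <- read_cell_table(cells, cancer_types = config$cancer_types,
                             pixel_to_um = config$pixel_to_um)
  } else if (inherits(cells, "image_table")) {
    cells <- list(cells)
  }
  clinical <- config$clinical
  if (is.character(clinical)) {
    if (!file.exists(clinical))
      stop_schema(paste0("clinical table not found: ", clinical))
    clinical <- read_clinical_table(clinical)
  }
  list(images = cells, clinical = clinical)
}

image_patient_map <- function(images) {
  data.frame(image_id = vapply(images, function(im) im$image_id[[1]], ""),
             patient_id = vapply(images, function(im) im$patient_id[[1]], ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

write_out <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Survival workflow: RD/NRD/abundance features to prognostic associations
#'
#' Computes per-image RD scores, NRD scores and abundance features,
#' aggregates them to patients, screens every feature family against overall
#' survival with Cox models and BH FDR, and summarizes the significant RD
#' pairs as a directed favorable-to-unfavorable network. Deterministic given
#' `config$seed`. Writes `rd.csv`, `nrd.csv`, `features.csv`, `assoc.csv`
#' and `network.json` when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @return List with `rd` (an `rd_score_set`), `nrd`, `features`, `assoc`
#'   (per feature family x feature), `network` (a `pair_network`).
#' @export
run_survival_workflow <- function(config) {
  inp <- load_inputs(config)
  set.seed(config$seed)
  images <- inp$images; clinical <- inp$clinical
  imap <- image_patient_map(images)

  rd <- rd_matrix(images, cap = config$cap)
  nrd <- nrd_matrix(images, cap = config$cap, n_perm = config$n_perm)
  feats <- feature_table(images, cap = config$cap)

  agg <- function(df) patient_level_aggregate(df, imap, policy = config$aggregate)
  rd_pat <- agg(rd)
  nrd_df <- data.frame(image_id = nrd$image_id, feature = nrd$pair,
                       value = nrd$nrd, stringsAsFactors = FALSE)
  nrd_pat <- agg(nrd_df[!is.na(nrd_df$value), , drop = FALSE])
  feat_pat <- agg(feats[!is.na(feats$value), , drop = FALSE])

  assoc <- rbind(
    cbind(family = "rd", assoc_survival(rd_pat, clinical, adjust = config$adjust),
          stringsAsFactors = FALSE),
    cbind(family = "nrd", assoc_survival(nrd_pat, clinical, adjust = config$adjust),
          stringsAsFactors = FALSE),
    cbind(family = "abundance",
          assoc_survival(feat_pat, clinical, adjust = config$adjust),
          stringsAsFactors = FALSE))

  rd_assoc <- assoc[assoc$family == "rd", , drop = FALSE]
  parts <- strsplit(rd_assoc$feature, "->", fixed = TRUE)
  rd_assoc$x_type <- vapply(parts, `[`, "", 1L)
  rd_assoc$y_type <- vapply(parts, `[`, "", 2L)
  network <- significant_pair_network(rd_assoc, fdr_threshold = config$fdr)

  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    write_scores(rd, file.path(config$out_dir, "rd.csv"))
    write_out(nrd, config$out_dir, "nrd.csv")
    write_out(feats, config$out_dir, "features.csv")
    write_out(assoc, config$out_dir, "assoc.csv")
    jsonlite::write_json(
      list(fdr_threshold = network$fdr_threshold, nodes = network$nodes,
           edges = network$edges),
      file.path(config$out_dir, "network.json"), auto_unbox = TRUE, digits = NA)
  }
  list(rd = rd, nrd = nrd, features = feats, assoc = assoc, network = network)
}

#' Response workflow: RD scores per cancer reference to AUC tables
#'
#' Filters patients to the requested arm and timepoint, computes RD scores of
#' the TME pair universe against the aggregate of all cancer cells and each
#' requested cancer subtype reference, aggregates to patients, and reports
#' rank-based AUC and AUC' per (pair, reference) for responder versus
#' non-responder classification. Writes `auc.csv` (with a `reference`
#' column) when `out_dir` is set.
#'
#' @param config a [run_config()]; `arm` selects the treatment arm and
#'   `timepoint` the sampling timepoint (default `"baseline"`).
#' @return Data frame `reference`, `feature`, `auc`, `auc_prime`, `n_pos`,
#'   `n_neg`.
#' @export
run_response_workflow <- function(config) {
  inp <- load_inputs(config)
  set.seed(config$seed)
  clinical <- inp$clinical
  keep <- rep(TRUE, nrow(clinical))
  if (!is.null(config$arm)) keep <- keep & clinical$arm == config$arm
  if (!is.null(config$timepoint) && "timepoint" %in% names(clinical))
    keep <- keep & (is.na(clinical$timepoint) |
                      clinical$timepoint == config$timepoint)
  clinical <- clinical[keep, , drop = FALSE]
  classes <- table(clinical$response[!is.na(clinical$response)])
  if (length(classes) < 2L || any(classes < 2L))
    stop_degenerate("arm/timepoint filter leaves fewer than two patients per response class")

  images <- inp$images
  images <- Filter(function(im) im$patient_id[[1]] %in% clinical$patient_id,
                   images)
  if (!length(images)) stop_degenerate("no images left after filtering")
  imap <- image_patient_map(images)

  refs <- rd_matrix_by_reference(images,
                                 tme_types = config$tme_types,
                                 reference_types = config$reference_types,
                                 include_aggregate = config$include_aggregate,
                                 cap = config$cap)
  out <- lapply(names(refs), function(ref) {
    pat <- patient_level_aggregate(refs[[ref]], imap, policy = "mean")
    cbind(reference = ref, assoc_response(pat, clinical),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  write_out(res, config$out_dir, "auc.csv")
  res
}
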