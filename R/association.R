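# ---- Association of features with survival and treatment response ----

# accept a named numeric vector or a data.frame(patient_id, value)
as_patient_values <- function(x) {
  if (is.data.frame(x)) {
    val_col <- first_col(x, c("value", "rd", "nrd", "score"))
    if (is.null(val_col) || !"patient_id" %in% names(x))
      stop_schema("feature data frame needs patient_id and a value column")
    setNames(x[[val_col]], x$patient_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop_schema("feature must be a named numeric vector or a data frame")
  }
}

join_survival <- function(values, clinical) {
  v <- as_patient_values(values)
  idx <- match(names(v), clinical$patient_id)
  df <- data.frame(patient_id = names(v), value = unname(v),
                   os_time = clinical$os_time[idx],
                   os_event = clinical$os_event[idx],
                   stringsAsFactors = FALSE)
  df[complete.cases(df[, c("value", "os_time", "os_event")]), , drop = FALSE]
}

#' Univariable Cox proportional-hazards association of one feature
#'
#' Fits `Surv(os_time, os_event) ~ feature` with Efron tie handling. By
#' default the feature is standardized per cohort SD so hazard ratios are
#' comparable across features on different scales.
#'
#' @param values per-patient feature values: a named numeric vector or a data
#'   frame with `patient_id` and a value column. Patients with missing
#'   feature or survival are dropped (reflected in `n_used`).
#' @param clinical a `clinical_table` (or data frame with `patient_id`,
#'   `os_time`, `os_event`).
#' @param feature_name label for the output row.
#' @param scale `"sd"` (default, HR per standard deviation) or `"unit"`.
#' @return One-row data frame: `feature`, `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `se`, `p_value`, `n_used`, `n_events`.
#' @export
cox_univariable <- function(values, clinical, feature_name = "feature",
                            scale = c("sd", "unit")) {
  scale <- match.arg(scale)
  df <- join_survival(values, clinical)
  if (var(df$value) == 0)
    stop_degenerate(paste0("feature ", feature_name, " has zero variance"))
  n_events <- sum(df$os_event)
  if (n_events < 10)
    warning("fewer than 10 events for feature ", feature_name, call. = FALSE)
  z <- if (scale == "sd") as.numeric(scale(df$value)) else df$value
  fit <- survival::coxph(survival::Surv(os_time, os_event) ~ z,
                         data = cbind(df, z = z), ties = "efron")
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(confint(fit))
  data.frame(feature = feature_name,
             hr = unname(exp(sm[1, "coef"])),
             ci_low = unname(exp(ci[1, 1])), ci_high = unname(exp(ci[1, 2])),
             log_hr = unname(sm[1, "coef"]), se = unname(sm[1, "se(coef)"]),
             p_value = unname(sm[1, "Pr(>|z|)"]),
             n_used = nrow(df), n_events = n_events,
             stringsAsFactors = FALSE)
}

#' Multivariable Cox association adjusted for clinical covariates
#'
#' As [cox_univariable()] but adjusting for the listed covariate columns of
#' the clinical table. Character covariates are treated as factors (one-hot
#' against the reference level, settable via `ref_levels`). Collinear
#' covariate columns are dropped with a warning.
#'
#' @inheritParams cox_univariable
#' @param covariates character vector of clinical column names to adjust for.
#' @param ref_levels optional named list of reference levels for categorical
#'   covariates.
#' @return One-row data frame (feature effect, adjusted), as
#'   [cox_univariable()] plus `covariates`.
#' @export
cox_multivariable <- function(values, clinical, covariates,
                              feature_name = "feature",
                              scale = c("sd", "unit"), ref_levels = NULL) {
  scale <- match.arg(scale)
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov))
    stop_schema(paste0("missing covariate column(s): ",
                       paste(missing_cov, collapse = ", ")))
  v <- as_patient_values(values)
  idx <- match(names(v), clinical$patient_id)
  df <- data.frame(value = unname(v),
                   os_time = clinical$os_time[idx],
                   os_event = clinical$os_event[idx],
                   stringsAsFactors = FALSE)
  for (cv in covariates) {
    col <- clinical[[cv]][idx]
    if (is.character(col)) {
      col <- factor(col)
      if (!is.null(ref_levels[[cv]])) col <- stats::relevel(col, ref_levels[[cv]])
    }
    df[[cv]] <- col
  }
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (var(df$value) == 0)
    stop_degenerate(paste0("feature ", feature_name, " has zero variance"))
  df$z <- if (scale == "sd") as.numeric(scale(df$value)) else df$value
  fml <- as.formula(paste("survival::Surv(os_time, os_event) ~ z +",
                          paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    warning("dropping collinear covariate term(s): ",
            paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(confint(fit))
  data.frame(feature = feature_name,
             hr = unname(exp(sm["z", "coef"])),
             ci_low = unname(exp(ci["z", 1])), ci_high = unname(exp(ci["z", 2])),
             log_hr = unname(sm["z", "coef"]), se = unname(sm["z", "se(coef)"]),
             p_value = unname(sm["z", "Pr(>|z|)"]),
             n_used = nrow(df), n_events = sum(df$os_event),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Median-split Kaplan-Meier comparison
#'
#' Dichotomizes patients at the median feature value (ties, including the
#' median itself, go to the low group) and compares survival with the
#' log-rank test.
#'
#' @inheritParams cox_univariable
#' @return List with `p_value` (log-rank), `n_low`, `n_high`, `cutoff`, and
#'   the `survival::survdiff` fit.
#' @export
km_median_split <- function(values, clinical) {
  df <- join_survival(values, clinical)
  if (length(unique(df$value)) < 2L)
    stop_degenerate("all feature values identical; no median split possible")
  cutoff <- median(df$value)
  df$group <- factor(ifelse(df$value <= cutoff, "low", "high"),
                     levels = c("low", "high"))
  sd_fit <- survival::survdiff(survival::Surv(os_time, os_event) ~ group,
                               data = df)
  p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  list(p_value = p, n_low = sum(df$group == "low"),
       n_high = sum(df$group == "high"), cutoff = cutoff, fit = sd_fit)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper over `p.adjust(..., method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return FDR-adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_config("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Linear regression of a score on clinical factors
#'
#' Ordinary least squares of a per-patient score on the listed clinical
#' covariates (the score ~ age + sex + BMI + smoking + stage + histology
#' style model). Rank-deficient designs are reported via a warning naming
#' the aliased terms.
#'
#' @inheritParams cox_univariable
#' @param covariates clinical column names to regress on.
#' @return Data frame of per-term `estimate`, `se`, `p_value` (intercept
#'   included).
#' @export
linreg_clinical <- function(values, clinical,
                            covariates = c("age", "sex", "bmi", "smoking",
                                           "stage", "histology")) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov))
    stop_schema(paste0("missing covariate column(s): ",
                       paste(missing_cov, collapse = ", ")))
  v <- as_patient_values(values)
  idx <- match(names(v), clinical$patient_id)
  df <- data.frame(score = unname(v), stringsAsFactors = FALSE)
  for (cv in covariates) {
    col <- clinical[[cv]][idx]
    df[[cv]] <- if (is.character(col)) factor(col) else col
  }
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(as.formula(paste("score ~", paste(covariates, collapse = " + "))),
            data = df)
  if (nrow(df) <= length(stats::coef(fit)))
    stop_degenerate("fewer observations than model columns")
  aliased <- names(which(summary(fit)$aliased))
  if (length(aliased))
    warning("rank-deficient design; aliased term(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"], p_value = sm[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group (or k-group) comparison of a continuous variable
#'
#' Student's t-test or Wilcoxon rank-sum for two groups; one-way ANOVA or
#' Kruskal-Wallis for more than two. Two-sided throughout.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param test `"t"` or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `n_per_group`, `method`.
#' @export
group_compare <- function(values, groups, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  tab <- table(groups)
  if (nlevels(groups) < 2L)
    stop_degenerate("need at least two non-empty groups")
  if (any(tab < 2L))
    stop_degenerate(paste0("group(s) with fewer than two values: ",
                           paste(names(tab)[tab < 2], collapse = ", ")))
  if (nlevels(groups) == 2L) {
    ht <- if (test == "t") t.test(values ~ groups)
          else suppressWarnings(wilcox.test(values ~ groups, exact = FALSE))
  } else {
    ht <- if (test == "t") oneway.test(values ~ groups, var.equal = TRUE)
          else kruskal.test(values ~ groups)
  }
  p <- ht$p.value
  # a fully tied comparison carries no evidence of a difference
  if (is.na(p) && length(unique(values)) == 1L) p <- 1
  list(statistic = unname(ht$statistic), p_value = p,
       n_per_group = as.integer(tab), method = ht$method)
}

#' Fisher's exact test of two categorical variables
#'
#' Thin utility around `fisher.test(table(x, y))`.
#'
#' @param x,y categorical vectors of equal length.
#' @return The p-value.
#' @export
fisher_association <- function(x, y) {
  fisher.test(table(x, y))$p.value
}

#' Rank-based AUC and rescaled AUC for a single feature
#'
#' Mann-Whitney AUC (ties contribute 1/2) of the feature for classifying the
#' positive class, plus the rescaled `AUC' = 0.5 + |AUC - 0.5|`, which folds
#' anti-correlated features onto the same `[0.5, 1]` effectiveness scale.
#'
#' @param values numeric feature values.
#' @param labels binary class labels (logical, 0/1, or a two-level factor /
#'   character vector).
#' @param positive the label counted as positive; default `TRUE`, `1`, or the
#'   second factor level.
#' @return One-row data frame: `auc`, `auc_prime`, `n_pos`, `n_neg`.
#' @export
auc_classify <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (is.logical(labels)) labels <- factor(labels, levels = c(FALSE, TRUE))
  else labels <- factor(as.character(labels))
  if (nlevels(droplevels(labels)) < 2L)
    stop_degenerate("both classes must be present")
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == as.character(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)                       # midranks handle ties at weight 1/2
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  data.frame(auc = auc, auc_prime = 0.5 + abs(auc - 0.5),
             n_pos = n1, n_neg = n0)
}

#' Aggregate per-image scores to per-patient feature values
#'
#' @param scores an `rd_score_set`, an NRD data frame, or any data frame with
#'   `image_id`, a feature key column (`pair` or `feature`) and a value
#'   column.
#' @param image_map data frame with `image_id`, `patient_id` covering every
#'   scored image.
#' @param policy `"mean"` (average replicate images per patient) or
#'   `"per_image"` (keep image replicates; patient label repeated).
#' @return Data frame `patient_id`, `feature`, `value` (plus `image_id` under
#'   `"per_image"`).
#' @export
patient_level_aggregate <- function(scores, image_map,
                                    policy = c("mean", "per_image")) {
  policy <- match.arg(policy)
  if (inherits(scores, "rd_score_set")) scores <- scores$scores
  key_col <- first_col(scores, c("pair", "feature"))
  val_col <- first_col(scores, c("rd", "nrd", "value", "score"))
  if (is.null(key_col) || is.null(val_col) || !"image_id" %in% names(scores))
    stop_schema("scores must have image_id, a pair/feature column and a value column")
  idx <- match(scores$image_id, image_map$image_id)
  if (anyNA(idx))
    stop_alignment(paste0("unmapped image id(s): ",
                          paste(unique(scores$image_id[is.na(idx)]), collapse = ", ")))
  df <- data.frame(patient_id = image_map$patient_id[idx],
                   image_id = scores$image_id,
                   feature = scores[[key_col]],
                   value = scores[[val_col]], stringsAsFactors = FALSE)
  if (policy == "per_image") return(df)
  out <- aggregate(value ~ patient_id + feature, data = df, FUN = mean,
                   na.action = stats::na.omit)
  out[order(out$feature, out$patient_id), c("patient_id", "feature", "value")]
}

#' Survival association screen over many features
#'
#' Univariable (and optionally covariate-adjusted) Cox models per feature,
#' with Benjamini-Hochberg FDR across features. Zero-variance features are
#' skipped with a warning.
#'
#' @param features data frame `patient_id`, `feature`, `value` (e.g. from
#'   [patient_level_aggregate()]).
#' @param clinical a `clinical_table`.
#' @param adjust optional covariate names for [cox_multivariable()].
#' @param scale see [cox_univariable()].
#' @return Data frame, one row per feature, with `fdr` appended.
#' @export
assoc_survival <- function(features, clinical, adjust = NULL, scale = "sd") {
  rows <- list(); skipped <- character(0)
  for (f in unique(features$feature)) {
    sub <- features[features$feature == f, , drop = FALSE]
    v <- setNames(sub$value, sub$patient_id)
    row <- tryCatch({
      suppressWarnings(
        if (is.null(adjust)) cox_univariable(v, clinical, feature_name = f, scale = scale)
        else cox_multivariable(v, clinical, covariates = adjust,
                               feature_name = f, scale = scale))
    }, proxiscore_degenerate_error = function(e) NULL)
    if (is.null(row)) skipped <- c(skipped, f) else rows[[f]] <- row
  }
  if (length(skipped))
    warning("skipped degenerate feature(s): ", paste(skipped, collapse = ", "),
            call. = FALSE)
  if (!length(rows)) stop_degenerate("no feature could be fitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Response-classification screen over many features
#'
#' Rank-based AUC and AUC' per feature against a binary response label.
#'
#' @param features data frame `patient_id`, `feature`, `value`.
#' @param clinical a `clinical_table` with a `response` column (positive
#'   class `"pCR"` by default).
#' @param positive response level treated as positive.
#' @return Data frame, one row per feature: `feature`, `auc`, `auc_prime`,
#'   `n_pos`, `n_neg`.
#' @export
assoc_response <- function(features, clinical, positive = "pCR") {
  rows <- lapply(unique(features$feature), function(f) {
    sub <- features[features$feature == f, , drop = FALSE]
    idx <- match(sub$patient_id, clinical$patient_id)
    res <- auc_classify(sub$value, clinical$response[idx], positive = positive)
    cbind(feature = f, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Directed network of prognostically significant cell pairs
#'
#' One edge per pair significant at the FDR threshold, oriented from the
#' favorable to the unfavorable cell type: for `RD(X->Y)` with HR > 1 a high
#' score (X relatively distant, Y relatively close to cancer) is hazardous,
#' so proximity of X is favorable and the edge runs X -> Y; with HR < 1 it
#' runs Y -> X.
#'
#' @param results data frame with columns `x_type`, `y_type`, `hr`, `fdr`
#'   (one row per canonical pair; e.g. [assoc_survival()] output joined back
#'   to its pair labels).
#' @param fdr_threshold significance cut-off (default 0.05).
#' @return A `pair_network`: list with `nodes` (type, in_degree, out_degree),
#'   `edges` (from, to, hr, fdr) and `fdr_threshold`.
#' @export
significant_pair_network <- function(results, fdr_threshold = 0.05) {
  for (col in c("x_type", "y_type", "hr", "fdr"))
    if (!col %in% names(results)) stop_schema(paste0("missing column: ", col))
  sig <- results[!is.na(results$fdr) & results$fdr < fdr_threshold, , drop = FALSE]
  edges <- data.frame(
    from = ifelse(sig$hr > 1, sig$x_type, sig$y_type),
    to = ifelse(sig$hr > 1, sig$y_type, sig$x_type),
    hr = sig$hr, fdr = sig$fdr, stringsAsFactors = FALSE)
  types <- sort(unique(c(results$x_type, results$y_type)))
  nodes <- data.frame(
    type = types,
    in_degree = vapply(types, function(t) sum(edges$to == t), integer(1)),
    out_degree = vapply(types, function(t) sum(edges$from == t), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, fdr_threshold = fdr_threshold),
            class = "pair_network")
}

#' @export
print.pair_network <- function(x, ...) {
  cat("Pair network: ", nrow(x$edges), " significant pair(s) at FDR < ",
      x$fdr_threshold, ", ", nrow(x$nodes), " cell type(s)\n", sep = "")
  invisible(x)
}
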