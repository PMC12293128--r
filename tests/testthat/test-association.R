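# direct outcome simulators (oracles independent of the cohort generator)

sim_survival <- function(z, beta, h0 = 0.02, cens_max = 120) {
  n <- length(z)
  t_event <- rexp(n, rate = h0 * exp(beta * z))
  t_cens <- runif(n, 0, cens_max)
  data.frame(patient_id = sprintf("p%03d", seq_len(n)),
             os_time = pmin(t_event, t_cens),
             os_event = as.numeric(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

named_z <- function(z) setNames(z, sprintf("p%03d", seq_along(z)))

test_that("univariable Cox recovers a known log-hazard and rejects degeneracy", {
  set.seed(101)
  z <- rnorm(400)
  clin <- sim_survival(z, beta = 0.8)
  fit <- cox_univariable(named_z(z), clin)
  expect_lt(abs(fit$log_hr - 0.8), 0.2)
  expect_true(fit$hr > 1 && fit$ci_low < fit$hr && fit$hr < fit$ci_high)
  expect_equal(fit$n_used, 400L)

  expect_error(cox_univariable(named_z(rep(1, 400)), clin),
               class = "proxiscore_degenerate_error")
})

test_that("univariable Cox holds its type-I error under the null", {
  set.seed(103)
  p <- replicate(200, {
    z <- rnorm(400)
    clin <- sim_survival(z, beta = 0)
    cox_univariable(named_z(z), clin)$p_value
  })
  expect_lte(mean(p < 0.05), 0.07)
  # and log-HRs stay near zero
  expect_lt(abs(mean(p) - 0.5), 0.12)
})

test_that("covariate adjustment leaves an independent effect unchanged and fixes confounding", {
  set.seed(107)
  z <- rnorm(400)
  cov_indep <- rnorm(400)
  clin <- sim_survival(z, beta = 0.6)
  clin$age <- cov_indep
  unadj <- cox_univariable(named_z(z), clin)
  adj <- cox_multivariable(named_z(z), clin, covariates = "age")
  expect_lt(abs(adj$log_hr - unadj$log_hr), 0.1)

  # confounder drives both the feature and the hazard; the feature itself is null
  u <- rnorm(400)
  feat <- u + rnorm(400, sd = 0.6)
  clin2 <- sim_survival(u, beta = 0.9)
  clin2$age <- u
  unadj2 <- cox_univariable(named_z(feat), clin2)
  adj2 <- cox_multivariable(named_z(feat), clin2, covariates = "age")
  expect_lt(abs(adj2$log_hr), abs(unadj2$log_hr))

  expect_error(cox_multivariable(named_z(feat), clin2, covariates = "bmi"),
               "bmi", class = "proxiscore_schema_error")
})

test_that("median-split KM detects strong effects and sends ties low", {
  set.seed(109)
  z <- rnorm(400)
  clin <- sim_survival(z, beta = 1.2)
  km <- km_median_split(named_z(z), clin)
  expect_lt(km$p_value, 0.01)
  expect_equal(km$n_low + km$n_high, 400L)

  vals <- c(1, 1, 1, 2, 3)
  clin5 <- sim_survival(rnorm(5), beta = 0)
  km5 <- km_median_split(setNames(vals, clin5$patient_id), clin5)
  expect_equal(km5$n_low, 3L)   # the median value itself goes low
  expect_equal(km5$n_high, 2L)

  expect_error(km_median_split(setNames(rep(2, 5), clin5$patient_id), clin5),
               class = "proxiscore_degenerate_error")
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "proxiscore_config_error")
})

test_that("linear regression on clinical factors recovers a known effect", {
  set.seed(113)
  n <- 400
  clin <- data.frame(patient_id = sprintf("p%03d", 1:n),
                     smoking = sample(c("never", "current"), n, TRUE),
                     age = rnorm(n, 65, 8), stringsAsFactors = FALSE)
  score <- 0.1 * (clin$smoking == "never") + rnorm(n, sd = 0.15)
  res <- linreg_clinical(setNames(score, clin$patient_id), clin,
                         covariates = c("smoking", "age"))
  eff <- res$estimate[res$term == "smokingnever"]
  expect_lt(abs(eff - 0.1), 0.04)

  # noise score: no covariate should be reliably significant
  set.seed(115)
  rej <- replicate(100, {
    score <- rnorm(n)
    res <- linreg_clinical(setNames(score, clin$patient_id), clin,
                           covariates = c("smoking", "age"))
    res$p_value[res$term == "age"] < 0.05
  })
  expect_lte(mean(rej), 0.12)

  tiny <- clin[1:2, ]
  expect_error(linreg_clinical(setNames(score[1:2], tiny$patient_id), tiny,
                               covariates = c("smoking", "age")),
               class = "proxiscore_degenerate_error")
})

test_that("group comparisons behave on ties, shifts and bad input", {
  ident <- group_compare(rep(1, 10), rep(c("a", "b"), 5), test = "wilcoxon")
  expect_equal(ident$p_value, 1)

  set.seed(117)
  vals <- c(rnorm(100), rnorm(100, mean = 1))
  grp <- rep(c("a", "b"), each = 100)
  expect_lt(group_compare(vals, grp, test = "t")$p_value, 0.01)
  expect_lt(group_compare(vals, grp, test = "wilcoxon")$p_value, 0.01)

  expect_error(group_compare(vals[1:100], grp[1:100]),
               class = "proxiscore_degenerate_error")
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")),
               class = "proxiscore_degenerate_error")

  k3 <- group_compare(rnorm(30), rep(c("a", "b", "c"), 10), test = "wilcoxon")
  expect_match(k3$method, "Kruskal")
})

test_that("rank AUC handles separation, ties and rescaling", {
  lab <- rep(c(FALSE, TRUE), each = 5)
  sep <- auc_classify(c(1:5, 6:10), lab)
  expect_equal(sep$auc, 1)
  expect_equal(sep$auc_prime, 1)
  anti <- auc_classify(c(6:10, 1:5), lab)
  expect_equal(anti$auc, 0)
  expect_equal(anti$auc_prime, 1)
  flat <- auc_classify(rep(3, 10), lab)
  expect_identical(flat$auc, 0.5)
  expect_error(auc_classify(1:5, rep(TRUE, 5)),
               class = "proxiscore_degenerate_error")
  # AUC'(feature) = AUC'(-feature)
  set.seed(119)
  v <- rnorm(60); l <- rbinom(60, 1, 0.5)
  expect_equal(auc_classify(v, l)$auc_prime, auc_classify(-v, l)$auc_prime)
})

test_that("rank AUC agrees with pROC on tied and untied data", {
  set.seed(121)
  v <- round(rnorm(150), 1)                 # induces ties
  l <- rbinom(150, 1, 0.5)
  got <- auc_classify(v, l, positive = "1")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(l, v, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the significant-pair network is oriented favorable -> unfavorable", {
  res <- data.frame(x_type = c("B", "B", "Tc"), y_type = c("IntMo", "Tc", "Th"),
                    hr = c(1.8, 0.6, 1.1), fdr = c(0.01, 0.03, 0.40),
                    stringsAsFactors = FALSE)
  net <- significant_pair_network(res, fdr_threshold = 0.05)
  expect_equal(nrow(net$edges), 2L)
  # RD(B->IntMo), HR > 1: B distant is hazardous, so proximity of B is
  # favorable and the edge runs B -> IntMo
  expect_true(any(net$edges$from == "B" & net$edges$to == "IntMo"))
  # RD(B->Tc), HR < 1: B distant is favorable, so proximity of Tc is
  # favorable and the edge runs Tc -> B
  expect_true(any(net$edges$from == "Tc" & net$edges$to == "B"))
  nb <- net$nodes[net$nodes$type == "B", ]
  expect_equal(nb$out_degree, 1L)
  expect_equal(nb$in_degree, 1L)

  empty <- significant_pair_network(res[res$fdr > 0.9, , drop = FALSE])
  expect_equal(nrow(empty$edges), 0L)
})

test_that("patient aggregation averages replicates and flags unmapped images", {
  sc <- data.frame(image_id = c("i1", "i2", "i3"), pair = "A->B",
                   rd = c(0.4, 0.6, 0.9), stringsAsFactors = FALSE)
  map <- data.frame(image_id = c("i1", "i2", "i3"),
                    patient_id = c("p1", "p1", "p2"), stringsAsFactors = FALSE)
  agg <- patient_level_aggregate(sc, map, policy = "mean")
  expect_equal(agg$value[agg$patient_id == "p1"], 0.5)
  per <- patient_level_aggregate(sc, map, policy = "per_image")
  expect_equal(nrow(per), 3L)
  # one image per patient: both policies coincide
  map1 <- data.frame(image_id = c("i1", "i2", "i3"),
                     patient_id = c("q1", "q2", "q3"), stringsAsFactors = FALSE)
  a <- patient_level_aggregate(sc, map1, policy = "mean")
  b <- patient_level_aggregate(sc, map1, policy = "per_image")
  expect_equal(sort(a$value), sort(b$value))

  expect_error(patient_level_aggregate(sc, map[-2, ], policy = "mean"),
               "i2", class = "proxiscore_alignment_error")
})

test_that("fisher utility returns a probability", {
  p <- fisher_association(rep(c("a", "b"), each = 10),
                          rep(c("x", "y"), 10))
  expect_true(p >= 0 && p <= 1)
})
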