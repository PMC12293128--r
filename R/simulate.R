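# ---- Synthetic cohorts with known spatial interactions and outcome effects ----

#' Simulation configuration
#'
#' Describes a synthetic cohort: a square field per image, a cancer-cell
#' point process, non-cancer types placed by distance-dependent thinning
#' around the cancer cells, and optional survival / response outcomes driven
#' by the RD score of one named ground-truth pair.
#'
#' Non-cancer placement: each type draws its realized count from
#' `Poisson(intensity x area)` and places the cells by rejection sampling
#' from a spatial density proportional to the interaction kernel evaluated at
#' the distance `d` to the nearest cancer cell: `exp(-d / tau)` (attract),
#' `1 - exp(-d / tau)` (exclude) or constant (neutral). Because the count is
#' drawn before placement, `intensity` is always the realized intensity and
#' abundance is independent of the interaction — changing `tau` changes
#' where cells sit, never how many there are. The exponential kernel is
#' one-parameter and sign-symmetric between attraction and exclusion; small
#' `tau` means a tighter halo around (or void near) cancer cells.
#'
#' @param n_patients number of patients.
#' @param images_per_patient a single count, or a length-2 range sampled
#'   uniformly per patient.
#' @param field_size square field side in micrometres.
#' @param cancer list: `types` (named numeric vector of intensities in
#'   cells/mm^2), `process` (`"poisson"` or `"clustered"`), and for the
#'   clustered (Thomas) process `parent_intensity` (parents/mm^2) and
#'   `cluster_sd` (um); mean offspring per parent is
#'   `intensity / parent_intensity`, so `types` always states the realized
#'   intensity.
#' @param type_specs named list, one entry per non-cancer type:
#'   `list(intensity = cells/mm^2, interaction = "neutral"|"attract"|"exclude",
#'   tau = um)`.
#' @param outcome list with optional `survival = list(pair, beta,
#'   baseline_hazard, censoring)` (exponential survival in months with
#'   per-SD log-hazard `beta` on the pair's RD and uniform censoring at the
#'   stated rate) and `response = list(pair, gamma or auc, rate)` (logistic
#'   response with per-SD log-odds `gamma`, or `auc`, a theoretical AUC the
#'   slope is solved for).
#' @param arms optional named list of treatment arms:
#'   `list(chemo = list(n = , rate = ), ...)`; arm response rates override
#'   `outcome$response$rate`.
#' @param seed optional integer seed; the whole cohort is deterministic
#'   given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100,
                       images_per_patient = 1,
                       field_size = 600,
                       cancer = list(types = c(Cancer = 400),
                                     process = "poisson"),
                       type_specs = list(
                         A = list(intensity = 200, interaction = "neutral"),
                         B = list(intensity = 200, interaction = "neutral")),
                       outcome = list(),
                       arms = NULL,
                       seed = NULL) {
  if (n_patients < 1) stop_config("n_patients must be positive")
  if (field_size <= 0) stop_config("field_size must be positive")
  if (any(unlist(cancer$types) <= 0)) stop_config("cancer intensities must be positive")
  for (nm in names(type_specs)) {
    ts <- type_specs[[nm]]
    ts$interaction <- ts$interaction %||% "neutral"
    if (!ts$interaction %in% c("neutral", "attract", "exclude"))
      stop_config(paste0("unknown interaction for type ", nm))
    if (is.null(ts$intensity) || ts$intensity <= 0)
      stop_config(paste0("intensity must be positive for type ", nm))
    if (ts$interaction != "neutral" && (is.null(ts$tau) || ts$tau <= 0))
      stop_config(paste0("tau must be positive for non-neutral type ", nm))
    type_specs[[nm]] <- ts
  }
  structure(list(n_patients = n_patients,
                 images_per_patient = images_per_patient,
                 field_size = field_size, cancer = cancer,
                 type_specs = type_specs, outcome = outcome,
                 arms = arms, seed = seed),
            class = "sim_config")
}

#' LUAD-like preset
#'
#' One image per treatment-naive patient, one cancer type plus 15 non-cancer
#' types (endothelial plus 14 immune types), overall survival driven by the
#' RD score of the B / intermediate-monocyte pair.
#'
#' @param n_patients cohort size (default 416, the LUAD study scale).
#' @param beta per-SD log-hazard on the ground-truth pair's RD.
#' @param ... overrides passed to [sim_config()].
#' @export
luad_sim_config <- function(n_patients = 416, beta = 0.5, ...) {
  imm <- function(intensity, interaction = "neutral", tau = NULL)
    list(intensity = intensity, interaction = interaction, tau = tau)
  defaults <- list(
    n_patients = n_patients, images_per_patient = 1, field_size = 700,
    cancer = list(types = c(Cancer = 800), process = "clustered",
                  parent_intensity = 25, cluster_sd = 40),
    type_specs = list(
      B = imm(90), Tc = imm(160, "attract", 60), Th = imm(140),
      Treg = imm(50, "attract", 80), Tother = imm(40, "neutral"),
      NK = imm(25), DC = imm(30), Mast = imm(20), Neutrophil = imm(60),
      ClMo = imm(70), NonClMo = imm(35), IntMo = imm(45, "attract", 70),
      AltMac = imm(120, "attract", 50), ClMac = imm(100),
      Endothelial = imm(180, "exclude", 60)),
    outcome = list(survival = list(pair = c("B", "IntMo"), beta = beta,
                                   baseline_hazard = 0.015, censoring = 0.4)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' TNBC-like preset
#'
#' Multi-image baseline samples from 279 patients in two arms (141 chemo with
#' a 62/141 response rate, 138 immunochemo with 67/138), 17 cancer subtypes
#' and 20 TME types.
#'
#' @param n_patients cohort size (default 279).
#' @param gamma per-SD log-odds of response on the ground-truth pair's RD
#'   (default 0: arm base rates only).
#' @param auc optional theoretical AUC target overriding `gamma`.
#' @param ... overrides passed to [sim_config()].
#' @export
tnbc_sim_config <- function(n_patients = 279, gamma = 0, auc = NULL, ...) {
  imm <- function(intensity, interaction = "neutral", tau = NULL)
    list(intensity = intensity, interaction = interaction, tau = tau)
  cancer_int <- setNames(rep(60, 17), paste0("Cancer_", sprintf("%02d", 1:17)))
  cancer_int[c("Cancer_01", "Cancer_02")] <- c(160, 120)
  tme <- list(
    Endothelial = imm(150, "exclude", 60), Fibroblast = imm(200),
    Myofibroblast = imm(80), PDPN_stromal = imm(40), CA9 = imm(30),
    B = imm(70), Tc = imm(120, "attract", 60), Th = imm(100),
    Treg = imm(45, "attract", 80), NK = imm(25), DC = imm(30),
    Mast = imm(15), Neutrophil = imm(50), ClMo = imm(60), IntMo = imm(35),
    NonClMo = imm(25), AltMac = imm(90, "attract", 50), ClMac = imm(80),
    PDL1_APC = imm(35), Undefined = imm(55))
  n_chemo <- round(n_patients * 141 / 279)
  defaults <- list(
    n_patients = n_patients, images_per_patient = c(1, 3), field_size = 600,
    cancer = list(types = cancer_int, process = "clustered",
                  parent_intensity = 30, cluster_sd = 35),
    type_specs = tme,
    outcome = list(response = list(pair = c("Endothelial", "Treg"),
                                   gamma = gamma, auc = auc)),
    arms = list(chemo = list(n = n_chemo, rate = 62 / 141),
                immunochemo = list(n = n_patients - n_chemo, rate = 67 / 138)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' Logistic slope achieving a target theoretical AUC
#'
#' For a standard-normal marker `z` and outcome `Y ~ Bernoulli(plogis(alpha +
#' gamma z))`, solves (by Gaussian quadrature and root finding) for the slope
#' `gamma` whose theoretical AUC of `z` for `Y` equals `auc`, with the
#' intercept set for the requested prevalence.
#'
#' @param auc target AUC in `(0.5, 1)`.
#' @param prevalence target `P(Y = 1)` (default 0.5).
#' @return The slope `gamma` (per SD of the marker).
#' @export
gamma_for_auc <- function(auc, prevalence = 0.5) {
  if (auc <= 0.5 || auc >= 1) stop_config("auc must lie in (0.5, 1)")
  zs <- seq(-8, 8, length.out = 2001)
  w <- dnorm(zs); w <- w / sum(w)
  alpha_for <- function(gamma) {
    uniroot(function(a) sum(w * plogis(a + gamma * zs)) - prevalence,
            c(-30, 30))$root
  }
  auc_of <- function(gamma) {
    p <- plogis(alpha_for(gamma) + gamma * zs)
    pi1 <- sum(w * p)
    f1 <- w * p / pi1
    f0 <- w * (1 - p) / (1 - pi1)
    sum(f1 * (cumsum(f0) - 0.5 * f0))
  }
  uniroot(function(g) auc_of(g) - auc, c(1e-4, 10))$root
}

# nearest-cancer distance for the placement kernel; a cap far beyond the
# field diagonal keeps the cap inactive
thinning_distance <- function(px, py, cx, cy, field_size) {
  .nn_capped_cpp(px, py, cx, cy, 4 * field_size)
}

#' Simulate one image
#'
#' @param config a [sim_config()].
#' @param image_id,sample_id,patient_id identifiers for the generated table.
#' @return An `image_table`; when the cancer process drew zero cells the
#'   attribute `no_cancer` is `TRUE` (downstream RD computation skips such
#'   images).
#' @export
simulate_image <- function(config, image_id = "img1", sample_id = image_id,
                           patient_id = image_id) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  L <- config$field_size
  area <- (L / 1000)^2
  cx <- numeric(0); cy <- numeric(0); ctype <- character(0)
  for (nm in names(config$cancer$types)) {
    lam <- config$cancer$types[[nm]]
    if (identical(config$cancer$process, "clustered")) {
      n_par <- rpois(1, config$cancer$parent_intensity * area)
      px <- runif(n_par, 0, L); py <- runif(n_par, 0, L)
      kid <- rpois(n_par, lam / max(config$cancer$parent_intensity, 1e-9))
      x <- rep(px, kid) + rnorm(sum(kid), 0, config$cancer$cluster_sd)
      y <- rep(py, kid) + rnorm(sum(kid), 0, config$cancer$cluster_sd)
      x <- x %% L; y <- y %% L            # toroidal wrap keeps intensity
    } else {
      n <- rpois(1, lam * area)
      x <- runif(n, 0, L); y <- runif(n, 0, L)
    }
    cx <- c(cx, x); cy <- c(cy, y); ctype <- c(ctype, rep(nm, length(x)))
  }
  nx <- numeric(0); ny <- numeric(0); ntype <- character(0)
  for (nm in names(config$type_specs)) {
    ts <- config$type_specs[[nm]]
    n_cells <- rpois(1, ts$intensity * area)
    if (n_cells == 0) next
    if (ts$interaction == "neutral" || length(cx) == 0L) {
      x <- runif(n_cells, 0, L); y <- runif(n_cells, 0, L)
    } else {
      # rejection sampling from the density proportional to the interaction
      # kernel; the realized count stays Poisson(intensity * area), so
      # abundance and interaction are independent knobs
      x <- numeric(0); y <- numeric(0)
      batches <- 0L
      while (length(x) < n_cells) {
        m <- max(4L * (n_cells - length(x)), 64L)
        px <- runif(m, 0, L); py <- runif(m, 0, L)
        d <- thinning_distance(px, py, cx, cy, L)
        p <- if (ts$interaction == "attract") exp(-d / ts$tau)
             else 1 - exp(-d / ts$tau)
        keep <- runif(m) < p
        x <- c(x, px[keep]); y <- c(y, py[keep])
        batches <- batches + 1L
        if (batches > 2000L)
          stop_degenerate(paste0("interaction kernel for type ", nm,
                                 " accepts almost no locations in this field"))
      }
      x <- x[seq_len(n_cells)]; y <- y[seq_len(n_cells)]
    }
    nx <- c(nx, x); ny <- c(ny, y)
    ntype <- c(ntype, rep(nm, n_cells))
  }
  img <- image_table(x = c(cx, nx), y = c(cy, ny),
                     cell_type = c(ctype, ntype),
                     cancer_types = names(config$cancer$types),
                     image_id = image_id, sample_id = sample_id,
                     patient_id = patient_id)
  attr(img, "no_cancer") <- length(cx) == 0L
  img
}

# uniform-censoring horizon hitting a target censoring fraction under the
# baseline exponential hazard
censor_horizon <- function(h0, censoring) {
  if (censoring <= 0) return(Inf)
  frac_censored <- function(cmax) (1 - exp(-h0 * cmax)) / (h0 * cmax)
  uniroot(function(cm) frac_censored(cm) - censoring,
          lower = 1e-8 / h0, upper = 1e8 / h0)$root
}

#' Simulate a cohort of images with clinical outcomes
#'
#' Generates all patients' images, computes the ground-truth pair's RD score
#' per patient (mean over that patient's scoreable images), standardizes it
#' across the cohort, and draws outcomes from it: exponential survival with
#' hazard `h0 * exp(beta * z)` under independent uniform censoring, and/or a
#' logistic response `Bernoulli(plogis(alpha + gamma * z))` with the
#' intercept solved per arm so the arm's response rate matches its target.
#' Independent clinical covariates (age, sex, BMI, smoking, stage, histology)
#' are always attached. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `images` (named list of `image_table`), `clinical`
#'   (a `clinical_table`) and `truth` (`pair`, `beta`, `gamma`, per-patient
#'   standardized `z`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  arm <- rep("none", n)
  if (!is.null(config$arms)) {
    arm <- rep(names(config$arms), vapply(config$arms, function(a) a$n, 1))
    if (length(arm) != n) stop_config("arm sizes must sum to n_patients")
    arm <- sample(arm)
  }

  ipp <- config$images_per_patient
  n_img <- if (length(ipp) == 2L) sample(ipp[1]:ipp[2], n, replace = TRUE)
           else rep(ipp, n)

  images <- list()
  surv_spec <- config$outcome$survival
  resp_spec <- config$outcome$response
  truth_pair <- (surv_spec$pair %||% resp_spec$pair) %||% NULL
  z_raw <- rep(NA_real_, n)
  cap <- 500
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (k in seq_len(n_img[i])) {
      id <- sprintf("img_%s_%d", pid[i], k)
      img <- simulate_image(config, image_id = id,
                            sample_id = sprintf("S_%s_%d", pid[i], k),
                            patient_id = pid[i])
      images[[id]] <- img
      if (!is.null(truth_pair) && !isTRUE(attr(img, "no_cancer"))) {
        dx <- mean_capped_distance(img, truth_pair[[1]], cap = cap)
        dy <- mean_capped_distance(img, truth_pair[[2]], cap = cap)
        vals <- c(vals, rd_score(dx, dy))
      }
    }
    if (length(vals)) z_raw[i] <- mean(vals)
  }
  z <- rep(0, n)
  if (!is.null(truth_pair)) {
    ok <- !is.na(z_raw)
    z[ok] <- (z_raw[ok] - mean(z_raw[ok])) / sd(z_raw[ok])
  }

  clin <- data.frame(
    patient_id = pid,
    os_time = NA_real_, os_event = NA_real_,
    age = round(rnorm(n, 67, 9)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    bmi = round(rnorm(n, 26, 4), 1),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.25, 0.45, 0.30)),
    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(0.55, 0.25, 0.20)),
    histology = sample(c("lepidic", "acinar", "papillary", "solid"), n,
                       replace = TRUE, prob = c(0.25, 0.35, 0.2, 0.2)),
    arm = arm, response = NA_character_, timepoint = "baseline",
    stringsAsFactors = FALSE)

  beta <- 0; gamma <- 0
  if (!is.null(surv_spec)) {
    beta <- surv_spec$beta %||% 0
    h0 <- surv_spec$baseline_hazard %||% 0.015
    censoring <- surv_spec$censoring %||% 0.4
    h <- h0 * exp(beta * z)
    t_event <- rexp(n, rate = h)
    cmax <- censor_horizon(h0, censoring)
    t_cens <- if (is.finite(cmax)) runif(n, 0, cmax) else rep(Inf, n)
    clin$os_time <- pmin(t_event, t_cens)
    clin$os_event <- as.numeric(t_event <= t_cens)
  }
  if (!is.null(resp_spec)) {
    gamma <- if (!is.null(resp_spec$auc)) gamma_for_auc(resp_spec$auc)
             else resp_spec$gamma %||% 0
    solve_alpha <- function(zz, rate) {
      if (gamma == 0) return(qlogis(rate))
      uniroot(function(a) mean(plogis(a + gamma * zz)) - rate, c(-30, 30))$root
    }
    resp <- rep(NA, n)
    if (!is.null(config$arms)) {
      for (a in names(config$arms)) {
        sel <- arm == a
        alpha <- solve_alpha(z[sel], config$arms[[a]]$rate)
        resp[sel] <- rbinom(sum(sel), 1, plogis(alpha + gamma * z[sel]))
      }
    } else {
      alpha <- solve_alpha(z, resp_spec$rate %||% 0.5)
      resp <- rbinom(n, 1, plogis(alpha + gamma * z))
      clin$arm <- "immunochemo"
    }
    clin$response <- ifelse(resp == 1, "pCR", "RD")
  }
  class(clin) <- c("clinical_table", "data.frame")
  list(images = images, clinical = clin,
       truth = list(pair = truth_pair, beta = beta, gamma = gamma,
                    z = setNames(z, pid)))
}
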