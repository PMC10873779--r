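#' Synthetic multi-site cohort specification
#'
#' Defines the generative model for the desk-scale demonstration cohort:
#' per patient, age (years), sex, arterial pH, a grayscale chest-image
#' proxy carrying a latent severity signal, and a binary in-hospital
#' mortality outcome drawn from a logistic model on the (population-)
#' standardized covariates. Site heterogeneity is planted as per-site
#' shifts of the covariate means and of the intercept.
#'
#' Defaults mirror the demonstration protocol: 4 sites of 1000 patients
#' each, split 40/10/50 into train/validation/test.
#'
#' @param n_sites number of sites.
#' @param n_per_site patients per site.
#' @param beta0 intercept of the logistic outcome model.
#' @param beta_age,beta_sex,beta_ph,beta_image log-odds coefficients on
#'   standardized age, male sex, standardized pH and the latent image
#'   severity.
#' @param site_intercept_shift,site_age_shift,site_ph_shift per-site
#'   additive shifts (length `n_sites`).
#' @param age_mean,age_sd,ph_mean,ph_sd covariate population parameters
#'   (pH clipped to `[6.8, 7.8]`).
#' @param p_male probability of male sex.
#' @param image_size side length of the square grayscale image.
#' @param split_fractions named train/validation/test fractions (sum 1).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sites = 4L, n_per_site = 1000L,
                        beta0 = -1.1, beta_age = 1.0, beta_sex = 0.5,
                        beta_ph = -1.2, beta_image = 1.0,
                        site_intercept_shift = c(-0.2, 0, 0.1, 0.2),
                        site_age_shift = c(-3, 0, 1, 3),
                        site_ph_shift = c(-0.02, 0, 0.01, 0.02),
                        age_mean = 64, age_sd = 15,
                        ph_mean = 7.40, ph_sd = 0.08,
                        p_male = 0.55,
                        image_size = 64L,
                        split_fractions = c(train = 0.4, validation = 0.1,
                                            test = 0.5),
                        seed = 1L) {
  stopifnot(is_count(n_sites), is_count(n_per_site),
            abs(sum(split_fractions) - 1) < 1e-9)
  recycle <- function(x) rep_len(x, n_sites)
  structure(list(
    n_sites = as.integer(n_sites), n_per_site = as.integer(n_per_site),
    beta0 = beta0, beta_age = beta_age, beta_sex = beta_sex,
    beta_ph = beta_ph, beta_image = beta_image,
    site_intercept_shift = recycle(site_intercept_shift),
    site_age_shift = recycle(site_age_shift),
    site_ph_shift = recycle(site_ph_shift),
    age_mean = age_mean, age_sd = age_sd, ph_mean = ph_mean, ph_sd = ph_sd,
    p_male = p_male, image_size = as.integer(image_size),
    split_fractions = split_fractions, seed = as.integer(seed)),
    class = "cohort_spec")
}

# one grayscale image: noisy background plus a central Gaussian blob whose
# peak intensity encodes the latent severity
synth_image <- function(severity, size, rng_noise = 0.03) {
  cx <- size / 2 + runif(1, -size / 8, size / 8)
  cy <- size / 2 + runif(1, -size / 8, size / 8)
  sig <- size / 8 * runif(1, 0.8, 1.2)
  gx <- outer(seq_len(size), seq_len(size), function(i, j)
    exp(-((i - cx)^2 + (j - cy)^2) / (2 * sig^2)))
  peak <- 0.45 + 0.15 * severity
  img <- 0.2 + peak * gx + matrix(rnorm(size^2, 0, rng_noise), size, size)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic multi-site cohort
#'
#' Deterministic given the spec seed. Returns per-site tabular data and
#' image stacks; the linear predictor uses population-standardized age
#' and pH so the planted coefficients are interpretable on a common
#' scale.
#'
#' @param spec a `cohort_spec`.
#' @return object of class `synthetic_cohort`: list of `sites`, each with
#'   `site_id`, `tab` (data.frame patient_id, age, sex, ph, severity,
#'   mortality, admission_time) and `images` (array size x size x 1 x n).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    sites <- lapply(seq_len(spec$n_sites), function(si) {
      n <- spec$n_per_site
      age <- round(rnorm(n, spec$age_mean + spec$site_age_shift[si],
                         spec$age_sd))
      age <- pmin(pmax(age, 18), 100)
      sex <- rbinom(n, 1, spec$p_male)  # 1 = male
      ph <- rnorm(n, spec$ph_mean + spec$site_ph_shift[si], spec$ph_sd)
      ph <- pmin(pmax(ph, 6.8), 7.8)
      severity <- rnorm(n)
      z_age <- (age - spec$age_mean) / spec$age_sd
      z_ph <- (ph - spec$ph_mean) / spec$ph_sd
      eta <- spec$beta0 + spec$site_intercept_shift[si] +
        spec$beta_age * z_age + spec$beta_sex * sex +
        spec$beta_ph * z_ph + spec$beta_image * severity
      mortality <- rbinom(n, 1, plogis(eta))
      images <- array(0, dim = c(spec$image_size, spec$image_size, 1L, n))
      for (i in seq_len(n))
        images[, , 1L, i] <- synth_image(severity[i], spec$image_size)
      admission <- format_iso8601(
        as.POSIXct("2023-01-01T00:00:00", tz = "UTC") +
          round(runif(n, 0, 364 * 86400)))
      list(site_id = sprintf("site-%d", si),
           tab = data.frame(
             patient_id = sprintf("s%d-p%04d", si, seq_len(n)),
             age = age, sex = sex, ph = round(ph, 3),
             severity = severity, mortality = mortality,
             admission_time = admission, stringsAsFactors = FALSE),
           images = images)
    })
    structure(list(sites = sites, spec = spec), class = "synthetic_cohort")
  })
}

LOINC_PH <- "2744-1"

#' Render a synthetic site as a FHIR store
#'
#' One Patient, one pH Observation (LOINC 2744-1) and one ImagingStudy per
#' patient; every emitted resource passes [validate_resource()].
#'
#' @param site one element of a `synthetic_cohort`'s `sites`.
#' @param image_dir directory referenced by the ImagingStudy resources.
#' @return a `site_store`.
#' @export
render_fhir <- function(site, image_dir = file.path("dicom",
                                                    site$site_id)) {
  tab <- site$tab
  res <- vector("list", 3L * nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pid <- tab$patient_id[i]
    res[[3 * i - 2]] <- fhir_patient(
      pid, gender_code(if (tab$sex[i] == 1) "male" else "female"),
      tab$age[i], deceased = tab$mortality[i] == 1)
    res[[3 * i - 1]] <- fhir_observation(
      paste0(pid, "-ph"), pid, loinc(LOINC_PH, "pH"),
      quantity(tab$ph[i], "[pH]"), tab$admission_time[i])
    res[[3 * i]] <- fhir_imaging_study(
      paste0(pid, "-img"), pid, "CR",
      file.path(image_dir, paste0(pid, ".dcm")), tab$admission_time[i])
  }
  site_store(site$site_id, res)
}

#' Render a synthetic site's images as DICOM files
#'
#' 8-bit grayscale secondary-capture files carrying only whitelisted
#' metadata, so [deidentify_dicom()] is a no-op on them.
#'
#' @param site one element of a `synthetic_cohort`'s `sites`.
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
render_dicom <- function(site, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(site$images)[4]
  paths <- character(n)
  for (i in seq_len(n)) {
    px <- round(site$images[, , 1L, i] * 255)
    ds <- dicom_create(
      px, modality = "CR",
      sop_instance_uid = sprintf("1.2.826.0.1.3680043.9999.%s.%d.1",
                                 sub("\\D+", "", site$site_id), i),
      study_uid = sprintf("1.2.826.0.1.3680043.9999.%s.%d.2",
                          sub("\\D+", "", site$site_id), i),
      series_uid = sprintf("1.2.826.0.1.3680043.9999.%s.%d.3",
                           sub("\\D+", "", site$site_id), i))
    paths[i] <- file.path(out_dir,
                          paste0(site$tab$patient_id[i], ".dcm"))
    write_dicom(ds, paths[i])
  }
  invisible(paths)
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive, outcome-stratified index sets; within each
#' outcome stratum the allocation is proportional with largest-remainder
#' rounding steered to hit the global split sizes exactly when they are
#' integers.
#'
#' @param y binary outcome vector.
#' @param fractions named fractions summing to 1 (default 40/10/50).
#' @param seed integer seed.
#' @return named list of integer index vectors.
#' @export
split_cohort <- function(y, fractions = c(train = 0.4, validation = 0.1,
                                          test = 0.5), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n <- length(y)
  strata <- split(seq_len(n), y)
  if (any(vapply(strata, length, 0L) < length(fractions)))
    stop("a stratum is smaller than the number of splits")
  # global split sizes by largest remainder, then per-stratum floors with
  # the leftover units assigned greedily to splits still short of their
  # global target (always feasible: stratum floors never exceed targets)
  raw <- n * fractions
  target <- floor(raw)
  rem <- order(raw - target, decreasing = TRUE)
  short <- n - sum(target)
  if (short > 0) target[rem[seq_len(short)]] <- target[rem[seq_len(short)]] + 1
  floors <- vapply(strata, function(s) floor(length(s) * fractions),
                   numeric(length(fractions)))
  floors <- matrix(floors, nrow = length(fractions))
  col_deficit <- target - rowSums(floors)
  out <- lapply(fractions, function(f) integer())
  with_seed(seed, {
    for (si in seq_along(strata)) {
      s <- sample(strata[[si]])
      ns <- length(s)
      alloc <- floors[, si]
      frac <- ns * fractions - alloc
      for (u in seq_len(ns - sum(alloc))) {
        j <- order(col_deficit > 0, frac, decreasing = TRUE)[1L]
        alloc[j] <- alloc[j] + 1
        col_deficit[j] <- col_deficit[j] - 1
        frac[j] <- frac[j] - 1
      }
      at <- 0L
      for (j in seq_along(fractions)) {
        if (alloc[j] > 0)
          out[[j]] <- c(out[[j]], s[(at + 1L):(at + alloc[j])])
        at <- at + alloc[j]
      }
    }
  })
  lapply(out, function(ix) sort(unname(ix)))
}
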