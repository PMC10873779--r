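#' Experiment configuration
#'
#' Ties together the cohort generator, model, training protocol and
#' analytics queries for an end-to-end run. The default is the desk-scale
#' demonstration: 4 synthetic sites of 250 patients, 40/10/50 split,
#' multi-input model, FedAVG with 4 local epochs for 10 rounds against a
#' pooled baseline with a matched total epoch budget.
#'
#' @param cohort a `cohort_spec`.
#' @param model a `model_spec`.
#' @param training a `training_config`.
#' @param k_suppression disclosure threshold for analytics queries.
#' @param output_dir where [render_report()] writes files.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(n_per_site = 250L),
                              model = model_spec(
                                image_input_shape = c(cohort$image_size,
                                                      cohort$image_size, 1L)),
                              training = training_config(
                                learning_rate = 3e-3, rounds = 10L,
                                epochs_per_round = 4L, batch_size = 32L,
                                seed = cohort$seed),
                              k_suppression = 5L,
                              output_dir = "fedmed-report") {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(model, "model_spec"),
            inherits(training, "training_config"),
            is_count(k_suppression, min = 2))
  structure(list(cohort = cohort, model = model, training = training,
                 k_suppression = k_suppression, output_dir = output_dir),
            class = "experiment_config")
}

# pooled z-score parameters from per-site train-split sufficient statistics
federated_standardization <- function(mats) {
  n <- sum(vapply(mats, nrow, 0L))
  sums <- Reduce(`+`, lapply(mats, colSums))
  sumsq <- Reduce(`+`, lapply(mats, function(m) colSums(m^2)))
  mu <- sums / n
  sdv <- sqrt(pmax((sumsq - sums^2 / n) / (n - 1), 1e-12))
  list(mean = mu, sd = sdv)
}

# assemble per-site model-ready data with federated standardization
prepare_fl_sites <- function(cohort, spec, k = 5L, seed = 1L) {
  sites_raw <- lapply(cohort$sites, function(s) {
    splits <- split_cohort(s$tab$mortality, cohort$spec$split_fractions,
                           seed = seed + match(s$site_id,
                                               vapply(cohort$sites, `[[`,
                                                      "", "site_id")))
    xtab <- cbind(age = s$tab$age, sex = s$tab$sex, ph = s$tab$ph)
    list(site = s, splits = splits, xtab = xtab)
  })
  std <- federated_standardization(
    lapply(sites_raw, function(sr) sr$xtab[sr$splits$train, , drop = FALSE]))
  lapply(sites_raw, function(sr) {
    z <- sweep(sweep(sr$xtab, 2L, std$mean), 2L, std$sd, `/`)
    mk <- function(idx) list(
      xtab = z[idx, , drop = FALSE],
      ximg = if (!is.null(spec$image_input_shape))
        sr$site$images[, , , idx, drop = FALSE],
      y = sr$site$tab$mortality[idx])
    site_node(sr$site$site_id,
              store = render_fhir(sr$site),
              fl_data = list(train = mk(sr$splits$train),
                             validation = mk(sr$splits$validation),
                             test = mk(sr$splits$test)),
              spec = spec)
  })
}

pool_split <- function(sites, split) {
  xt <- do.call(rbind, lapply(sites, function(s) s$fl_data[[split]]$xtab))
  imgs <- lapply(sites, function(s) s$fl_data[[split]]$ximg)
  xi <- if (!is.null(imgs[[1]])) {
    d <- dim(imgs[[1]])
    arr <- array(0, dim = c(d[1:3], sum(vapply(imgs, function(a) dim(a)[4],
                                               0L))))
    at <- 0L
    for (a in imgs) {
      arr[, , , (at + 1L):(at + dim(a)[4])] <- a
      at <- at + dim(a)[4]
    }
    arr
  }
  list(xtab = xt, ximg = xi,
       y = unlist(lapply(sites, function(s) s$fl_data[[split]]$y)))
}

#' Run the end-to-end federated experiment
#'
#' Generates the synthetic multi-site cohort, stands up simulated site
#' nodes, runs disclosure-controlled analytics queries with meta-analysis,
#' trains the multi-input model federatively (FedAVG) and as a pooled
#' baseline with a matched epoch budget, and evaluates both arms on the
#' identical pooled test split. Fully seeded and reproducible.
#'
#' @param config an `experiment_config`.
#' @return object of class `experiment_report`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort)
  sites <- prepare_fl_sites(cohort, config$model, k = config$k_suppression,
                            seed = config$cohort$seed)
  hub <- federation_hub()
  k <- config$k_suppression

  ph_sel <- resource_selector("Observation", code_filter = loinc(LOINC_PH))
  summ <- hub_summarize(hub, sites, ph_sel, k = k)
  sex_part <- partition_categorical(
    resource_selector("Patient", field = "gender"))
  brk <- hub_breakdown(hub, sites, ph_sel, sex_part, k = k)
  meta <- meta_analyze(estimates_from_summaries(summ$per_site))

  fed <- run_training(hub, sites, config$model, config$training)
  pooled_train <- pool_split(sites, "train")
  pooled_val <- pool_split(sites, "validation")
  pooled_fit <- train_centralized(
    list(train = pooled_train, validation = pooled_val),
    config$model, config$training)

  test <- pool_split(sites, "test")
  eval_arm <- function(weights) {
    p <- forward_pass(weights, config$model, test$xtab, test$ximg)$p
    compute_metrics(test$y, p)
  }
  fed_metrics <- eval_arm(fed$weights)
  pooled_metrics <- eval_arm(pooled_fit$weights)

  audit <- audit_entries(hub$log)
  structure(list(
    config = config,
    analytics = list(per_site = summ$per_site, pooled = summ$pooled,
                     breakdown = brk, meta = meta),
    federated = list(history = fed$history, metrics = fed_metrics,
                     weights = fed$weights),
    pooled_arm = list(history = pooled_fit$history,
                      metrics = pooled_metrics,
                      weights = pooled_fit$weights),
    test_n = length(test$y),
    audit_summary = list(n_messages = nrow(audit),
                         n_accepted = sum(audit$accepted),
                         n_rejected = sum(!audit$accepted)),
    audit_log = hub$log), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Federated experiment report\n")
  cat(sprintf("  sites: %d x %d patients; test n = %d\n",
              x$config$cohort$n_sites, x$config$cohort$n_per_site,
              x$test_n))
  cat(sprintf("  federated: AUC %.3f  F1 %.3f  loss %.4f\n",
              x$federated$metrics$auc, x$federated$metrics$f1,
              x$federated$metrics$loss))
  cat(sprintf("  pooled:    AUC %.3f  F1 %.3f  loss %.4f\n",
              x$pooled_arm$metrics$auc, x$pooled_arm$metrics$f1,
              x$pooled_arm$metrics$loss))
  cat(sprintf("  audit log: %d messages (%d accepted)\n",
              x$audit_summary$n_messages, x$audit_summary$n_accepted))
  invisible(x)
}

report_to_list <- function(report) {
  metr <- function(m) list(auc = m$auc, f1 = m$f1, loss = m$loss,
                           roc = m$roc, pr = m$pr)
  list(
    cohort = list(n_sites = report$config$cohort$n_sites,
                  n_per_site = report$config$cohort$n_per_site,
                  split = as.list(report$config$cohort$split_fractions)),
    analytics = list(
      per_site = lapply(report$analytics$per_site, summary_to_list),
      pooled = summary_to_list(report$analytics$pooled),
      breakdown = lapply(report$analytics$breakdown, breakdown_to_list),
      meta = list(pooled_estimate = report$analytics$meta$pooled_estimate,
                  tau_sq = report$analytics$meta$tau_sq,
                  q_statistic = report$analytics$meta$q_statistic,
                  ci95 = c(report$analytics$meta$ci95_low,
                           report$analytics$meta$ci95_high))),
    federated = list(history = report$federated$history,
                     metrics = metr(report$federated$metrics)),
    pooled_arm = list(history = report$pooled_arm$history,
                      metrics = metr(report$pooled_arm$metrics)),
    test_n = report$test_n,
    audit = report$audit_summary)
}

#' Render an experiment report to static files
#'
#' Writes a machine-readable JSON report plus loss-curve, ROC, PR and
#' per-site summary plots. Suppressed bins are rendered as the string
#' `"suppressed"`, never as numbers.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @param formats subset of `c("json", "png")`.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(report, dir = report$config$output_dir,
                          formats = c("json", "png")) {
  stopifnot(inherits(report, "experiment_report"))
  bad <- setdiff(formats, c("json", "png"))
  if (length(bad)) stop("unknown report format: ", paste(bad, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
    files <- c(files, path)
  }
  if ("png" %in% formats) {
    fed <- report$federated; pl <- report$pooled_arm
    p1 <- file.path(dir, "loss-curves.png")
    png(p1, width = 720, height = 480)
    rng <- range(c(fed$history$train_loss, fed$history$val_loss,
                   pl$history$train_loss, pl$history$val_loss),
                 na.rm = TRUE)
    ep_fed <- fed$history$round *
      report$config$training$epochs_per_round
    plot(ep_fed, fed$history$train_loss, type = "l", col = "firebrick",
         ylim = rng, xlab = "epoch budget", ylab = "BCE loss",
         main = "Training curves: federated vs pooled")
    lines(ep_fed, fed$history$val_loss, col = "firebrick", lty = 2)
    lines(pl$history$epoch, pl$history$train_loss, col = "navy")
    lines(pl$history$epoch, pl$history$val_loss, col = "navy", lty = 2)
    legend("topright", c("fed train", "fed val", "pooled train",
                         "pooled val"),
           col = c("firebrick", "firebrick", "navy", "navy"),
           lty = c(1, 2, 1, 2), bty = "n")
    dev.off()
    p2 <- file.path(dir, "roc.png")
    png(p2, width = 480, height = 480)
    plot(fed$metrics$roc$fpr, fed$metrics$roc$tpr, type = "l",
         col = "firebrick", xlab = "FPR", ylab = "TPR", main = "ROC")
    lines(pl$metrics$roc$fpr, pl$metrics$roc$tpr, col = "navy")
    abline(0, 1, lty = 3)
    legend("bottomright",
           sprintf("%s AUC=%.3f", c("federated", "pooled"),
                   c(fed$metrics$auc, pl$metrics$auc)),
           col = c("firebrick", "navy"), lty = 1, bty = "n")
    dev.off()
    p3 <- file.path(dir, "pr.png")
    png(p3, width = 480, height = 480)
    plot(fed$metrics$pr$recall, fed$metrics$pr$precision, type = "l",
         col = "firebrick", xlab = "recall", ylab = "precision",
         main = "Precision-recall", ylim = c(0, 1))
    lines(pl$metrics$pr$recall, pl$metrics$pr$precision, col = "navy")
    legend("bottomleft", c("federated", "pooled"),
           col = c("firebrick", "navy"), lty = 1, bty = "n")
    dev.off()
    p4 <- file.path(dir, "per-site-ph.png")
    png(p4, width = 600, height = 480)
    ps <- report$analytics$per_site
    means <- vapply(ps, function(s)
      if (s$suppressed) NA_real_ else s$mean, 0)
    bp <- barplot(means, names.arg = names(ps), col = "steelblue",
                  ylab = "mean pH",
                  ylim = range(c(7.3, 7.5, means), na.rm = TRUE),
                  xpd = FALSE, main = "Per-site mean pH (95% CI)")
    for (i in seq_along(ps)) {
      s <- ps[[i]]
      if (s$suppressed) text(bp[i], 7.31, "suppressed", srt = 90)
      else {
        lines(rep(bp[i], 2), c(s$ci95_low, s$ci95_high))
      }
    }
    dev.off()
    files <- c(files, p1, p2, p3, p4)
  }
  invisible(files)
}
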