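test_that("message validation enforces whitelist, schema and hub-centricity", {
  reg <- operation_registry()
  log <- audit_log()
  ok <- new_message("summarize",
                    list(selector = ph_selector(), k = 5L,
                         exchange_id = "q1"), "hub", "site-a")
  v <- validate_message(ok, reg, log)
  expect_true(v$accepted)

  bad_op <- new_message("raw_record_dump", list(), "hub", "site-a")
  v2 <- validate_message(bad_op, reg, log)
  expect_false(v2$accepted)
  expect_match(v2$reason, "not whitelisted")

  missing_field <- new_message("summarize", list(k = 5L), "hub", "site-a")
  v3 <- validate_message(missing_field, reg, log)
  expect_false(v3$accepted)
  expect_match(v3$reason, "schema violation")

  site_to_site <- new_message("summarize",
                              list(selector = ph_selector(), k = 5L,
                                   exchange_id = "q"), "site-a", "site-b")
  v4 <- validate_message(site_to_site, reg, log)
  expect_false(v4$accepted)
  expect_match(v4$reason, "inter-site")

  # every verdict was logged, in order, and no site-to-site entry accepted
  df <- audit_entries(log)
  expect_equal(nrow(df), 4L)
  expect_identical(df$accepted, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("aggregate_summaries pools sufficient statistics exactly", {
  t1 <- sufficient_statistics(value_store(1:3, "a"), ph_selector(), k = 2L)
  t2 <- sufficient_statistics(value_store(4:5, "b"), ph_selector(), k = 2L)
  pooled <- aggregate_summaries(list(t1, t2))
  expect_equal(pooled$n, 5L)
  expect_equal(pooled$mean, 3)
  expect_equal(pooled$sd, sqrt(2.5))
  # permutation invariance
  pooled2 <- aggregate_summaries(list(t2, t1))
  expect_equal(pooled2$mean, pooled$mean)
  expect_equal(pooled2$sd, pooled$sd)
  # single-site identity with the site's own summary
  own <- summarize_query(value_store(1:5, "a"), ph_selector(), k = 5L)
  one <- aggregate_summaries(list(
    sufficient_statistics(value_store(1:5, "a"), ph_selector(), k = 5L)))
  expect_equal(one$mean, own$mean)
  expect_equal(one$ci95_low, own$ci95_low)
  # suppressed sites are excluded and reported; all-suppressed pools suppress
  supp <- list(site_id = "c", suppressed = TRUE)
  mixed <- aggregate_summaries(list(t1, supp))
  expect_equal(mixed$n, 3L)
  expect_identical(mixed$excluded_sites, "c")
  expect_true(aggregate_summaries(list(supp))$suppressed)
})

test_that("meta_analyze follows the DerSimonian-Laird algebra", {
  single <- meta_analyze(data.frame(site_id = "a", estimate = 2,
                                    variance = 0.25))
  expect_equal(single$pooled_estimate, 2)
  expect_equal(single$tau_sq, 0)
  expect_equal(single$ci95_low, 2 - qnorm(.975) * .5, tolerance = 1e-12)
  expect_equal(single$ci95_low, 1.02, tolerance = 1e-2)
  expect_equal(single$ci95_high, 2.98, tolerance = 1e-2)

  two <- meta_analyze(data.frame(site_id = c("a", "b"),
                                 estimate = c(1, 2), variance = c(.5, .5)))
  expect_equal(two$q_statistic, 1)
  expect_equal(two$tau_sq, 0)       # Q - df = 0
  expect_equal(two$pooled_estimate, 1.5)
  expect_equal(two$pooled_estimate, two$fixed_effect)

  expect_error(meta_analyze(data.frame(estimate = 1, variance = 0)),
               "positive")
})

test_that("homogeneous studies reduce to the fixed-effect estimate", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    v <- runif(k, .2, .6)
    theta <- rnorm(k, 1, 0.05)  # tight: Q typically <= k-1
    m <- meta_analyze(data.frame(estimate = theta, variance = v))
    if (m$tau_sq == 0)
      expect_equal(m$pooled_estimate, sum(theta / v) / sum(1 / v),
                   tolerance = 1e-12)
    expect_true(m$ci95_low <= m$pooled_estimate &
                  m$pooled_estimate <= m$ci95_high)
  }
})

test_that("meta_analyze matches metafor's DL fit on random study sets", {
  skip_if_not_installed("metafor")
  set.seed(6)
  for (i in 1:40) {
    k <- sample(2:10, 1)
    yi <- rnorm(k, 0.5, 1)
    vi <- runif(k, 0.05, 1)
    m <- meta_analyze(data.frame(estimate = yi, variance = vi))
    r <- suppressWarnings(metafor::rma(yi, vi, method = "DL", test = "z"))
    expect_equal(m$pooled_estimate, as.numeric(r$beta), tolerance = 1e-10)
    expect_equal(m$tau_sq, r$tau2, tolerance = 1e-10)
    expect_equal(m$q_statistic, r$QE, tolerance = 1e-10)
    expect_equal(m$ci95_low, r$ci.lb, tolerance = 1e-10)
    expect_equal(m$ci95_high, r$ci.ub, tolerance = 1e-10)
  }
})

test_that("federated_average is a sample-size-weighted tensor mean", {
  u1 <- list(weights = list(w = c(0, 0)), n_samples = 1L)
  u2 <- list(weights = list(w = c(2, 2)), n_samples = 3L)
  expect_equal(federated_average(list(u1, u2))$w, c(1.5, 1.5))
  # single update: identity
  expect_equal(federated_average(list(u2))$w, c(2, 2))
  # equal n: unweighted mean; permutation invariant; idempotent on clones
  u3 <- list(weights = list(w = c(4, 6)), n_samples = 3L)
  expect_equal(federated_average(list(u2, u3))$w, c(3, 4))
  expect_equal(federated_average(list(u3, u2))$w, c(3, 4))
  expect_equal(federated_average(list(u3, u3, u3))$w, u3$weights$w)
  expect_equal(federated_average(list(u2, u3), average = "unweighted")$w,
               c(3, 4))
  bad <- list(weights = list(w = c(1, 2, 3)), n_samples = 1L)
  expect_error(federated_average(list(u1, bad)), "shape mismatch")
  expect_error(federated_average(list()), "no site updates")
})

test_that("a training round logs exactly two messages per site", {
  spec <- model_spec(tabular_input_dim = 2L, image_input_shape = NULL,
                     tabular_units = integer(0), merge_units = integer(0))
  set.seed(8)
  sites <- lapply(1:3, function(i) {
    d <- random_tab_data(20, d = 2L, seed = i)
    site_node(sprintf("site-%d", i),
              fl_data = list(train = d, validation = d), spec = spec)
  })
  hub <- federation_hub()
  w <- build_model(spec, seed = 1)
  cfg <- training_config(optimizer = "sgd", learning_rate = .1,
                         batch_size = Inf, seed = 1)
  before <- nrow(audit_entries(hub$log))
  rr <- run_round(hub, sites, w, epochs = 1L, config = cfg)
  after <- nrow(audit_entries(hub$log))
  expect_equal(after - before, 2L * length(sites))
  expect_equal(nrow(rr$updates), 3L)
  expect_identical(rr$updates$n_samples, rep(20L, 3))

  # an empty site abstains without killing the round
  sites2 <- c(sites, list(site_node("site-4", fl_data = list(
    train = list(xtab = NULL, ximg = NULL, y = NULL)), spec = spec)))
  rr2 <- run_round(hub, sites2, w, 1L, cfg)
  expect_true(rr2$updates$abstained[4])
  expect_equal(rr2$weights$out_w, rr$weights$out_w)
})

test_that("replaying the audit log reproduces hub outputs", {
  spec <- model_spec(tabular_input_dim = 2L, image_input_shape = NULL,
                     tabular_units = integer(0), merge_units = integer(0))
  sites <- lapply(1:2, function(i) {
    site_node(sprintf("site-%d", i),
              store = value_store(seq(7, 7.5, length.out = 5 + i),
                                  sprintf("site-%d", i)),
              fl_data = list(train = random_tab_data(15, 2L, i),
                             validation = random_tab_data(8, 2L, i + 10)),
              spec = spec)
  })
  hub <- federation_hub()
  q <- hub_summarize(hub, sites, ph_selector(), k = 5L)
  w <- build_model(spec, seed = 2)
  cfg <- training_config(optimizer = "sgd", learning_rate = .05,
                         batch_size = Inf, seed = 2)
  rr <- run_round(hub, sites, w, 1L, cfg)

  rp <- replay_audit(hub$log)
  expect_true(all(rp$verdicts))
  expect_length(rp$pooled, 1L)
  expect_equal(rp$pooled[[1]]$mean, q$pooled$mean, tolerance = 1e-12)
  expect_equal(rp$pooled[[1]]$n, q$pooled$n)
  expect_length(rp$averages, 1L)
  expect_equal(rp$averages[[1]], rr$weights, tolerance = 1e-15)
})

test_that("federated training improves validation loss on planted signal", {
  spec <- model_spec(tabular_input_dim = 3L, image_input_shape = NULL,
                     tabular_units = 4L, merge_units = integer(0))
  ch <- generate_cohort(cohort_spec(n_sites = 4L, n_per_site = 60L,
                                    beta_image = 0, seed = 14L))
  sites <- fedmed:::prepare_fl_sites(ch, spec, seed = 14L)
  hub <- federation_hub()
  cfg <- training_config(learning_rate = 0.02, rounds = 6L,
                         epochs_per_round = 4L, batch_size = 16L,
                         seed = 14L)
  fit <- run_training(hub, sites, spec, cfg)
  expect_equal(nrow(fit$history), 6L)
  expect_lt(fit$history$val_loss[6], fit$history$val_loss[1])
  # rerun reproduces the history exactly
  fit2 <- run_training(federation_hub(), sites, spec, cfg)
  expect_identical(fit$history, fit2$history)
})
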