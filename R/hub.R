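# Orchestration hub: whitelisted, schema-validated, audited exchanges with
# site nodes over an in-process message bus. The hub only ever handles
# aggregates (summary triples, study estimates, weight tensors) — never a
# site store.

#' Operation registry (whitelist + payload schemas)
#'
#' Loads the versioned operation whitelist shipped with the package. Every
#' message must name a whitelisted operation and carry all of its required
#' payload fields to be executed.
#'
#' @param path JSON schema document (defaults to the bundled one).
#' @return object of class `operation_registry`.
#' @export
operation_registry <- function(path = system.file("schema",
                                                  "operations.json",
                                                  package = "fedmed")) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(version = doc$version, operations = doc$operations),
            class = "operation_registry")
}

#' Append-only audit log
#'
#' Every hub/site exchange is recorded with its validation verdict. The
#' log API only appends; prior entries are never mutated. Site-to-site
#' entries cannot exist because validation rejects any message in which
#' neither party is the hub.
#'
#' @return object of class `audit_log`.
#' @export
audit_log <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- list()
  class(e) <- "audit_log"
  e
}

log_append <- function(log, msg, accepted, reason = NA_character_) {
  stopifnot(inherits(log, "audit_log"))
  log$entries[[length(log$entries) + 1L]] <-
    list(message = msg, accepted = accepted, reason = reason)
  invisible(log)
}

#' @rdname audit_log
#' @param log an `audit_log`.
#' @return data.frame view of the log entries.
#' @export
audit_entries <- function(log) {
  if (!length(log$entries))
    return(data.frame(message_id = character(), op_name = character(),
                      sender = character(), recipient = character(),
                      timestamp = character(), accepted = logical(),
                      reason = character()))
  do.call(rbind, lapply(log$entries, function(e)
    data.frame(message_id = e$message$message_id,
               op_name = e$message$op_name %||% NA_character_,
               sender = e$message$sender %||% NA_character_,
               recipient = e$message$recipient %||% NA_character_,
               timestamp = e$message$timestamp,
               accepted = e$accepted, reason = e$reason,
               stringsAsFactors = FALSE)))
}

#' @export
print.audit_log <- function(x, ...) {
  df <- audit_entries(x)
  cat(sprintf("<audit_log> %d entries (%d accepted, %d rejected)\n",
              nrow(df), sum(df$accepted), sum(!df$accepted)))
  invisible(x)
}

message_counter <- local({
  n <- 0L
  function() { n <<- n + 1L; n }
})

#' Construct a protocol message
#' @param op_name operation name (must be whitelisted to be executed).
#' @param payload named list conforming to the operation's schema.
#' @param sender,recipient `"hub"` or a site id; exactly one side of every
#'   exchange must be the hub.
#' @return object of class `fed_message`.
#' @export
new_message <- function(op_name, payload, sender, recipient) {
  structure(list(message_id = sprintf("msg-%06d", message_counter()),
                 op_name = op_name, payload = payload, sender = sender,
                 recipient = recipient,
                 timestamp = format_iso8601(Sys.time())),
            class = "fed_message")
}

#' Validate a message against the whitelist and its payload schema
#'
#' The verdict (accepted or rejected, with reason) is always appended to
#' the audit log; rejection is a verdict, not an error.
#'
#' @param msg a `fed_message`.
#' @param registry an `operation_registry`.
#' @param log an `audit_log`.
#' @return list `accepted` (logical), `reason`.
#' @export
validate_message <- function(msg, registry, log) {
  verdict <- function(ok, reason = NA_character_) {
    log_append(log, msg, ok, reason)
    list(accepted = ok, reason = reason)
  }
  if (!is_string(msg$op_name %||% NULL))
    return(verdict(FALSE, "missing op_name"))
  op <- registry$operations[[msg$op_name]]
  if (is.null(op))
    return(verdict(FALSE, sprintf("operation '%s' is not whitelisted",
                                  msg$op_name)))
  if (!is_string(msg$sender %||% NULL) || !is_string(msg$recipient %||% NULL))
    return(verdict(FALSE, "missing sender/recipient"))
  if (sum(c(msg$sender, msg$recipient) == "hub") != 1L)
    return(verdict(FALSE,
                   "inter-site communication is not permitted: exactly one party must be the hub"))
  required <- unlist(op$required)
  missing <- setdiff(required, names(msg$payload))
  if (length(missing))
    return(verdict(FALSE, sprintf("payload schema violation: missing %s",
                                  paste(missing, collapse = ", "))))
  verdict(TRUE)
}

#' Simulated site node
#'
#' Holds a site's de-identified store and (optionally) its local training
#' data; the only component with patient-level access. `fl_data` is a list
#' with elements `train`, `validation`, `test`, each `list(xtab, ximg,
#' y)`.
#'
#' @param site_id site identifier.
#' @param store a `site_store` (for analytics queries).
#' @param fl_data local model-training splits.
#' @param spec `model_spec` agreed across the federation.
#' @return object of class `fed_site`.
#' @export
site_node <- function(site_id, store = NULL, fl_data = NULL, spec = NULL) {
  structure(list(site_id = site_id, store = store, fl_data = fl_data,
                 spec = spec), class = "fed_site")
}

# site-side execution of an accepted hub request
site_execute <- function(site, msg) {
  p <- msg$payload
  switch(msg$op_name,
    summarize = list(op = "summary_result",
                     payload = list(summary = summarize_query(
                       site$store, p$selector, k = p$k),
                       exchange_id = p$exchange_id)),
    breakdown = list(op = "breakdown_result",
                     payload = list(breakdown = breakdown_query(
                       site$store, p$selector, p$partition, k = p$k),
                       exchange_id = p$exchange_id)),
    sufficient_statistics = list(op = "sufficient_statistics_result",
                                 payload = list(stats = sufficient_statistics(
                                   site$store, p$selector, k = p$k),
                                   exchange_id = p$exchange_id)),
    train_round = list(op = "site_update",
                       payload = list(update = local_train(
                         p$weights, site$spec, site$fl_data$train,
                         p$epochs, p$config),
                         exchange_id = p$exchange_id)),
    evaluate = list(op = "evaluation_result",
                    payload = list(metrics = local_evaluate(
                      p$weights, site$spec, site$fl_data[[p$split]]),
                      exchange_id = p$exchange_id)),
    stop("site has no handler for operation ", msg$op_name)
  )
}

#' Orchestration hub
#' @param registry an `operation_registry`.
#' @param log an `audit_log`.
#' @return object of class `fed_hub`.
#' @export
federation_hub <- function(registry = operation_registry(),
                           log = audit_log()) {
  structure(list(registry = registry, log = log), class = "fed_hub")
}

# one validated request/response exchange with a site
hub_exchange <- function(hub, site, op, payload) {
  req <- new_message(op, payload, sender = "hub", recipient = site$site_id)
  v <- validate_message(req, hub$registry, hub$log)
  if (!v$accepted) stop("protocol error: ", v$reason)
  resp <- site_execute(site, req)
  rmsg <- new_message(resp$op, resp$payload, sender = site$site_id,
                      recipient = "hub")
  v2 <- validate_message(rmsg, hub$registry, hub$log)
  if (!v2$accepted) stop("protocol error in site response: ", v2$reason)
  resp$payload
}

#' Pool per-site sufficient statistics exactly
#'
#' Pooled `n = sum n_i`, `mean = sum(sum_i)/n`, `sd = sqrt((sum(sumsq_i) -
#' (sum(sum_i))^2/n) / (n - 1))`, with the same CI construction as the
#' sites. Suppressed sites are excluded and reported; if every site is
#' suppressed the pooled result is suppressed too.
#'
#' @param triples list of [sufficient_statistics()] payloads.
#' @param ci `"normal"` or `"t"`.
#' @return a `summary_statistics` with an `excluded_sites` field.
#' @export
aggregate_summaries <- function(triples, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  suppressed <- vapply(triples, function(t) isTRUE(t$suppressed), logical(1))
  excluded <- vapply(triples[suppressed], function(t)
    t$site_id %||% NA_character_, "")
  use <- triples[!suppressed]
  if (!length(use)) {
    out <- suppressed_summary()
    out$excluded_sites <- excluded
    return(out)
  }
  n <- sum(vapply(use, `[[`, 0, "n"))
  if (n == 0) {
    out <- structure(list(suppressed = FALSE, n = 0L),
                     class = "summary_statistics")
    out$excluded_sites <- excluded
    return(out)
  }
  s <- sum(vapply(use, `[[`, 0, "sum"))
  ss <- sum(vapply(use, `[[`, 0, "sum_sq"))
  m <- s / n
  sdv <- if (n > 1) sqrt(max(0, (ss - s^2 / n) / (n - 1))) else NA_real_
  z <- if (ci == "normal") qnorm(0.975) else qt(0.975, df = n - 1)
  se <- sdv / sqrt(n)
  structure(list(suppressed = FALSE, n = n, sum = s, sum_sq = ss,
                 mean = m, sd = sdv, ci95_low = m - z * se,
                 ci95_high = m + z * se, excluded_sites = excluded),
            class = "summary_statistics")
}

#' Run a summarize query across the federation
#'
#' Per-site summaries plus the exact pooled summary reconstructed from
#' sufficient statistics; all exchanges are validated and audited.
#'
#' @param hub a `fed_hub`.
#' @param sites list of `fed_site`.
#' @param sel a `resource_selector`.
#' @param k suppression threshold.
#' @param pooled also pool via sufficient statistics (continuous only).
#' @return list `per_site` (named summaries), `pooled`.
#' @export
hub_summarize <- function(hub, sites, sel, k = 5L, pooled = TRUE) {
  ex_id <- sprintf("qry-%06d", message_counter())
  per_site <- lapply(sites, function(s)
    hub_exchange(hub, s, "summarize",
                 list(selector = sel, k = k, exchange_id = ex_id))$summary)
  names(per_site) <- vapply(sites, `[[`, "", "site_id")
  pooled_res <- NULL
  if (pooled) {
    triples <- lapply(sites, function(s)
      hub_exchange(hub, s, "sufficient_statistics",
                   list(selector = sel, k = k,
                        exchange_id = ex_id))$stats)
    pooled_res <- aggregate_summaries(triples)
  }
  list(per_site = per_site, pooled = pooled_res, exchange_id = ex_id)
}

#' Run a breakdown query across the federation
#' @inheritParams hub_summarize
#' @param partition a partition descriptor.
#' @return named list of per-site `breakdown_result`s.
#' @export
hub_breakdown <- function(hub, sites, sel, partition, k = 5L) {
  ex_id <- sprintf("qry-%06d", message_counter())
  out <- lapply(sites, function(s)
    hub_exchange(hub, s, "breakdown",
                 list(selector = sel, partition = partition, k = k,
                      exchange_id = ex_id))$breakdown)
  names(out) <- vapply(sites, `[[`, "", "site_id")
  out
}

#' Average site model updates (FedAVG step)
#'
#' Tensor-wise average of site weights, weighted by local sample size
#' (`w = sum(n_i w_i) / sum(n_i)`); an unweighted mean is available for
#' sensitivity checks. All tensors must agree in shape.
#'
#' @param updates list of site updates (`weights`, `n_samples`); abstained
#'   updates are not allowed here.
#' @param average `"weighted"` or `"unweighted"`.
#' @return averaged `model_weights`.
#' @export
federated_average <- function(updates, average = c("weighted",
                                                   "unweighted")) {
  average <- match.arg(average)
  if (!length(updates)) stop("no site updates to average")
  ref <- updates[[1]]$weights
  for (u in updates) {
    if (!identical(names(u$weights), names(ref)))
      stop("protocol error: site update tensors do not match")
    for (nm in names(ref))
      if (!identical(dim(u$weights[[nm]]) %||% length(u$weights[[nm]]),
                     dim(ref[[nm]]) %||% length(ref[[nm]])))
        stop("protocol error: tensor shape mismatch in ", nm)
    if (!is_count(u$n_samples)) stop("site update missing n_samples")
  }
  wts <- as.numeric(vapply(updates, `[[`, 0, "n_samples"))
  if (average == "unweighted") wts <- rep(1, length(updates))
  wts <- wts / sum(wts)
  out <- ref
  for (nm in names(ref)) {
    acc <- updates[[1]]$weights[[nm]] * wts[1]
    if (length(updates) > 1)
      for (i in 2:length(updates))
        acc <- acc + updates[[i]]$weights[[nm]] * wts[i]
    out[[nm]] <- acc
  }
  out
}

#' One federated training round
#'
#' Broadcasts the global weights, collects site updates (all exchanges
#' validated and audited: exactly two log entries per site per round),
#' and returns the federated average. A site failure aborts the round;
#' sites with no local data abstain and are excluded from the average.
#'
#' @param hub a `fed_hub`.
#' @param sites list of `fed_site` sharing a `model_spec`.
#' @param weights current global `model_weights`.
#' @param epochs local epochs (1 = FedSGD, > 1 = FedAVG).
#' @param config `training_config`.
#' @return list `weights`, `updates` (per-site `n_samples`, `local_loss`,
#'   `abstained`).
#' @export
run_round <- function(hub, sites, weights, epochs, config) {
  ex_id <- sprintf("rnd-%06d", message_counter())
  updates <- lapply(sites, function(s)
    hub_exchange(hub, s, "train_round",
                 list(weights = weights, epochs = epochs, config = config,
                      exchange_id = ex_id))$update)
  names(updates) <- vapply(sites, `[[`, "", "site_id")
  active <- Filter(function(u) !isTRUE(u$abstained), updates)
  if (!length(active)) stop("all sites abstained; no updates to average")
  new_weights <- federated_average(active, average = config$average)
  info <- data.frame(
    site_id = names(updates),
    n_samples = vapply(updates, function(u) u$n_samples %||% 0L, 0L),
    local_loss = vapply(updates, function(u) u$local_loss %||% NA_real_, 0),
    abstained = vapply(updates, function(u) isTRUE(u$abstained), logical(1)))
  list(weights = new_weights, updates = info, exchange_id = ex_id)
}

#' Federated training (FedSGD / FedAVG)
#'
#' Iterates [run_round()] for `config$rounds` rounds with
#' `config$epochs_per_round` local epochs, recording per-round training
#' loss (sample-size-weighted mean of site losses) and validation loss
#' (weighted mean of site-local validation losses). Deterministic given
#' the config seed.
#'
#' @inheritParams run_round
#' @param spec `model_spec` (weights are initialized from it when
#'   `init_weights` is NULL).
#' @param init_weights optional starting weights.
#' @return list `weights`, `history` (data.frame round/train_loss/
#'   val_loss).
#' @export
run_training <- function(hub, sites, spec, config, init_weights = NULL) {
  weights <- init_weights %||% build_model(spec, seed = config$seed)
  hist <- data.frame(round = seq_len(config$rounds),
                     train_loss = NA_real_, val_loss = NA_real_)
  for (r in seq_len(config$rounds)) {
    rr <- run_round(hub, sites, weights, config$epochs_per_round, config)
    weights <- rr$weights
    act <- rr$updates[!rr$updates$abstained, ]
    hist$train_loss[r] <- sum(act$local_loss * act$n_samples) /
      sum(act$n_samples)
    vals <- lapply(sites, function(s) {
      if (data_size(s$fl_data$validation) == 0) return(NULL)
      hub_exchange(hub, s, "evaluate",
                   list(weights = weights, split = "validation",
                        exchange_id = rr$exchange_id))$metrics
    })
    vals <- vals[!vapply(vals, is.null, logical(1))]
    if (length(vals)) {
      vn <- vapply(vals, `[[`, 0, "n")
      vl <- vapply(vals, `[[`, 0, "loss")
      hist$val_loss[r] <- sum(vl * vn) / sum(vn)
    }
    if (!is.finite(hist$train_loss[r]))
      stop("divergent training loss at round ", r)
  }
  list(weights = weights, history = hist)
}

#' Replay an audit log
#'
#' Re-validates every logged message against a registry and re-executes
#' the hub-side aggregation of logged site responses (federated averages
#' from `site_update` payloads, pooled summaries from
#' `sufficient_statistics_result` payloads). Because the hub is
#' deterministic given its inputs, replaying the log reproduces its
#' outputs exactly.
#'
#' @param log an `audit_log`.
#' @param registry an `operation_registry`.
#' @param average averaging mode used during the original run.
#' @return list `verdicts` (logical vector, one per entry), `averages`
#'   (per training exchange), `pooled` (per query exchange).
#' @export
replay_audit <- function(log, registry = operation_registry(),
                         average = "weighted") {
  fresh <- audit_log()
  verdicts <- vapply(log$entries, function(e)
    validate_message(e$message, registry, fresh)$accepted, logical(1))
  accepted <- lapply(log$entries[verdicts], `[[`, "message")
  by_exchange <- function(op) {
    msgs <- Filter(function(m) identical(m$op_name, op), accepted)
    split(msgs, vapply(msgs, function(m) m$payload$exchange_id, ""))
  }
  averages <- lapply(by_exchange("site_update"), function(msgs) {
    ups <- Filter(function(u) !isTRUE(u$abstained),
                  lapply(msgs, function(m) m$payload$update))
    federated_average(ups, average = average)
  })
  pooled <- lapply(by_exchange("sufficient_statistics_result"),
                   function(msgs)
                     aggregate_summaries(lapply(msgs, function(m)
                       m$payload$stats)))
  list(verdicts = verdicts, averages = averages, pooled = pooled)
}
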