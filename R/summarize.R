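#' Disclosure-safe summary statistics
#'
#' Constructor used by [summarize_query()] and [aggregate_summaries()].
#' When a result would be computed over fewer than `k` patients it carries
#' only a suppression flag — no counts or values.
#'
#' @param values numeric or categorical vector, one entry per patient.
#' @param k minimum number of patients that may be revealed (default 5).
#' @param ci `"normal"` for mean +/- 1.96 SE (default) or `"t"` for a
#'   Student-t interval.
#' @return object of class `summary_statistics`.
#' @export
summary_statistics <- function(values, k = 5L, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  n <- length(values)
  if (n > 0 && n < k) return(suppressed_summary())
  if (n == 0)
    return(structure(list(suppressed = FALSE, n = 0L),
                     class = "summary_statistics"))
  if (is.numeric(values)) {
    m <- mean(values)
    s <- sd(values)  # sample SD, n-1 denominator
    z <- if (ci == "normal") qnorm(0.975) else qt(0.975, df = n - 1)
    se <- s / sqrt(n)
    # the median is site-local information only: there is no exact
    # order-statistic merge from aggregates, so it is never pooled
    structure(list(suppressed = FALSE, n = n, sum = sum(values),
                   sum_sq = sum(values^2), mean = m, sd = s,
                   median = stats::median(values),
                   ci95_low = m - z * se, ci95_high = m + z * se),
              class = "summary_statistics")
  } else {
    tab <- table(as.character(values))
    tab <- tab[order(names(tab))]
    top <- which(tab == max(tab))
    structure(list(suppressed = FALSE, n = n,
                   categorical = setNames(as.integer(tab), names(tab)),
                   mode = names(tab)[top[1L]],  # lexicographic tie-break
                   mode_tied = length(top) > 1L),
              class = "summary_statistics")
  }
}

suppressed_summary <- function() {
  structure(list(suppressed = TRUE, n = 0L), class = "summary_statistics")
}

#' @export
print.summary_statistics <- function(x, ...) {
  if (x$suppressed) {
    cat("<summary> suppressed (fewer than k patients)\n")
  } else if (!is.null(x$categorical)) {
    cat(sprintf("<summary> n=%d mode=%s%s\n", x$n, x$mode,
                if (isTRUE(x$mode_tied)) " (tied)" else ""))
    print(x$categorical)
  } else if (x$n == 0) {
    cat("<summary> n=0 (empty)\n")
  } else {
    cat(sprintf("<summary> n=%d mean=%.4g sd=%.4g CI95=[%.4g, %.4g]\n",
                x$n, x$mean, x$sd, x$ci95_low, x$ci95_high))
  }
  invisible(x)
}

#' Site-level summarize query
#'
#' Computes record counts plus mean, sample SD and 95% CI for continuous
#' variables, or level counts and the mode for categorical variables, over
#' the per-patient values selected by `sel`. Results covering fewer than
#' `k` patients are suppressed in full.
#'
#' @param store a `site_store`.
#' @param sel a `resource_selector` (per-patient policy `latest` or
#'   `earliest`).
#' @param k suppression threshold.
#' @inheritParams summary_statistics
#' @return a `summary_statistics`.
#' @export
summarize_query <- function(store, sel, k = 5L, ci = "normal") {
  stopifnot(is_count(k, min = 2))
  if (identical(sel$resource_type, "ImagingStudy"))
    stop("ImagingStudy payloads are not summarizable")
  tab <- extract_variable(store, sel)
  summary_statistics(tab$value, k = k, ci = ci)
}

#' Sufficient statistics for exact cross-site pooling
#'
#' Returns the `(n, sum, sum_sq)` triple from which the hub reconstructs
#' pooled mean/SD exactly; non-disclosive for `n >= k`, suppressed below.
#'
#' @inheritParams summarize_query
#' @return list with `site_id`, `suppressed` and (if not suppressed)
#'   `n`, `sum`, `sum_sq`.
#' @export
sufficient_statistics <- function(store, sel, k = 5L) {
  tab <- extract_variable(store, sel)
  if (!is.numeric(tab$value))
    stop("sufficient statistics require a continuous variable")
  n <- nrow(tab)
  if (n > 0 && n < k)
    return(list(site_id = store$site_id, suppressed = TRUE))
  list(site_id = store$site_id, suppressed = FALSE, n = n,
       sum = sum(tab$value), sum_sq = sum(tab$value^2))
}

#' Partition descriptors for breakdown queries
#'
#' `partition_categorical()` partitions patients by a categorical variable
#' extracted with a selector (e.g. Patient gender). `partition_time()`
#' partitions the selected records into contiguous half-open `[start,
#' end)` bins of fixed width.
#'
#' @param sel selector extracting one categorical value per patient.
#' @return a partition descriptor for [breakdown_query()].
#' @export
partition_categorical <- function(sel) {
  stopifnot(inherits(sel, "resource_selector"))
  structure(list(type = "categorical", sel = sel), class = "fa_partition")
}

#' @rdname partition_categorical
#' @param start,end ISO 8601 bounds of the partitioned period.
#' @param width_days bin width in days.
#' @export
partition_time <- function(start, end, width_days = 7) {
  stopifnot(all(is_iso8601(c(start, end))), width_days > 0)
  structure(list(type = "time", start = start, end = end,
                 width_days = width_days), class = "fa_partition")
}

#' Site-level breakdown query
#'
#' Summary statistics on one variable partitioned by a categorical
#' variable or a time interval. The per-bin minimum is enforced at the
#' site: any bin with `0 < n < k` is transmitted as a bare suppression
#' marker (its true count is kept only in a site-local attribute used by
#' internal accounting, never serialized). Empty bins are reported with
#' `n = 0`, unsuppressed.
#'
#' @inheritParams summarize_query
#' @param partition a descriptor from [partition_categorical()] or
#'   [partition_time()].
#' @return object of class `breakdown_result`: ordered list of bins.
#' @export
breakdown_query <- function(store, sel, partition, k = 5L, ci = "normal") {
  stopifnot(inherits(partition, "fa_partition"))
  tab <- extract_variable(store, sel)
  if (partition$type == "categorical") {
    part <- extract_variable(store, partition$sel)
    if (is.numeric(part$value))
      stop("categorical partition over a continuous variable; ",
           "use partition_time() or a categorical selector")
    lev <- sort(unique(as.character(part$value)))
    groups <- setNames(lapply(lev, function(lv) {
      pids <- part$patient_id[part$value == lv]
      tab$value[tab$patient_id %in% pids]
    }), lev)
  } else {
    t0 <- parse_iso8601(partition$start)
    t1 <- parse_iso8601(partition$end)
    edges <- seq(from = as.numeric(t0), to = as.numeric(t1),
                 by = partition$width_days * 86400)
    if (edges[length(edges)] < as.numeric(t1))
      edges <- c(edges, edges[length(edges)] + partition$width_days * 86400)
    tt <- as.numeric(parse_iso8601(tab$time))
    keep <- !is.na(tt) & tt >= edges[1] & tt < edges[length(edges)]
    bin_of <- findInterval(tt[keep], edges, rightmost.closed = FALSE)
    labels <- vapply(seq_len(length(edges) - 1L), function(b)
      paste0("[", format_iso8601(as.POSIXct(edges[b], origin = "1970-01-01",
                                            tz = "UTC")),
             ", ", format_iso8601(as.POSIXct(edges[b + 1L],
                                             origin = "1970-01-01",
                                             tz = "UTC")), ")"), "")
    groups <- setNames(lapply(seq_len(length(edges) - 1L), function(b)
      tab$value[keep][bin_of == b]), labels)
  }
  bins <- lapply(groups, function(v) {
    s <- summary_statistics(v, k = k, ci = ci)
    if (s$suppressed) attr(s, "n_hidden") <- length(v)
    s
  })
  structure(list(partition = partition, k = k, bins = bins),
            class = "breakdown_result")
}

#' @export
print.breakdown_result <- function(x, ...) {
  cat(sprintf("<breakdown> %d bins (k=%d)\n", length(x$bins), x$k))
  for (nm in names(x$bins)) {
    b <- x$bins[[nm]]
    cat(" ", nm, ": ")
    if (b$suppressed) cat("suppressed\n")
    else if (!is.null(b$categorical)) cat("n=", b$n, " mode=", b$mode, "\n",
                                          sep = "")
    else if (b$n == 0) cat("n=0\n")
    else cat(sprintf("n=%d mean=%.4g sd=%.4g\n", b$n, b$mean, b$sd))
  }
  invisible(x)
}

# JSON-safe view: suppression renders as {"suppressed": true} and nothing
# else; internal attributes (hidden counts) are dropped.
summary_to_list <- function(s) {
  if (s$suppressed) return(list(suppressed = TRUE))
  out <- unclass(s)
  if (!is.null(out$categorical)) out$categorical <- as.list(out$categorical)
  attributes(out) <- list(names = names(out))
  out
}

breakdown_to_list <- function(b) {
  list(partition_type = b$partition$type, k = b$k,
       bins = lapply(b$bins, summary_to_list))
}
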