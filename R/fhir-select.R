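#' Declarative resource selector
#'
#' Describes which resource/code/value/time slice a query targets. All
#' filters are conjunctive. Time windows are half-open `[start, end)` so a
#' record timestamped exactly at `end` is excluded and adjacent windows
#' never double-count.
#'
#' @param resource_type one of the six modeled types.
#' @param code_filter optional `coded_value`; match is on (system, code).
#' @param value_range optional numeric `c(low, high)`, closed; only valid
#'   for Observation quantity values.
#' @param time_window optional `c(start, end)` ISO 8601 strings, half-open.
#' @param patient_filter optional predicate `function(patient) -> logical`
#'   applied to the subject Patient resource.
#' @param per_patient_policy how [extract_variable()] reduces multiple
#'   matches per patient: `"latest"` (default), `"earliest"` or `"all"`
#'   (`"all"` is only meaningful for [select_resources()]).
#' @param field for `resource_type = "Patient"`, which demographic field to
#'   extract: `"gender"`, `"age_years"` or `"deceased"`.
#' @return an object of class `resource_selector`.
#' @examples
#' ph_sel <- resource_selector("Observation", code_filter = loinc("2744-1"))
#' @export
resource_selector <- function(resource_type,
                              code_filter = NULL,
                              value_range = NULL,
                              time_window = NULL,
                              patient_filter = NULL,
                              per_patient_policy = c("latest", "earliest",
                                                     "all"),
                              field = NULL) {
  per_patient_policy <- match.arg(per_patient_policy)
  if (!(resource_type %in% FHIR_TYPES))
    stop("unknown resource type: ", resource_type)
  if (!is.null(value_range)) {
    if (!identical(resource_type, "Observation"))
      stop("value_range is only valid for Observation selectors")
    stopifnot(is.numeric(value_range), length(value_range) == 2L,
              value_range[1] <= value_range[2])
  }
  if (!is.null(time_window)) {
    stopifnot(length(time_window) == 2L)
    if (!all(is_iso8601(time_window)))
      stop("time_window bounds must be ISO 8601")
    if (parse_iso8601(time_window[1]) >= parse_iso8601(time_window[2]))
      stop("time_window must satisfy start < end")
  }
  if (!is.null(patient_filter)) stopifnot(is.function(patient_filter))
  if (!is.null(field)) {
    if (!identical(resource_type, "Patient"))
      stop("field is only valid for Patient selectors")
    field <- match.arg(field, c("gender", "age_years", "deceased"))
  }
  structure(list(resource_type = resource_type, code_filter = code_filter,
                 value_range = value_range, time_window = time_window,
                 patient_filter = patient_filter,
                 per_patient_policy = per_patient_policy, field = field),
            class = "resource_selector")
}

resource_time <- function(r) {
  switch(r$resource_type,
         Encounter = r$period_start,
         r$effective_time)
}

#' Select resources matching a selector
#'
#' Applies all of the selector's filters conjunctively and returns the
#' matching resources (the per-patient reduction policy is applied by
#' [extract_variable()], not here).
#'
#' @param store a `site_store`.
#' @param sel a `resource_selector`.
#' @return list of matching `fhir_resource` objects.
#' @export
select_resources <- function(store, sel) {
  stopifnot(inherits(store, "site_store"),
            inherits(sel, "resource_selector"))
  res <- store_by_type(store, sel$resource_type)
  if (!is.null(sel$code_filter))
    res <- Filter(function(r) !is.null(r$code) &&
                    same_code(r$code, sel$code_filter), res)
  if (!is.null(sel$value_range))
    res <- Filter(function(r) inherits(r$value, "quantity") &&
                    r$value$value >= sel$value_range[1] &&
                    r$value$value <= sel$value_range[2], res)
  if (!is.null(sel$time_window)) {
    t0 <- parse_iso8601(sel$time_window[1])
    t1 <- parse_iso8601(sel$time_window[2])
    res <- Filter(function(r) {
      tt <- resource_time(r)
      !is.null(tt) && {
        t <- parse_iso8601(tt)
        !is.na(t) && t >= t0 && t < t1
      }
    }, res)
  }
  if (!is.null(sel$patient_filter)) {
    pats <- store_patients(store)
    keep_pat <- vapply(pats, function(p) isTRUE(sel$patient_filter(p)),
                       logical(1))
    keep_ids <- names(pats)[keep_pat]
    res <- Filter(function(r) {
      pid <- if (identical(r$resource_type, "Patient")) r$id else r$subject_ref
      pid %in% keep_ids
    }, res)
  }
  res
}

#' Extract one value per patient for a selector
#'
#' Reduces the selection to a per-patient value table using the selector's
#' `per_patient_policy` (`latest` or `earliest`, resolved on the resource
#' timestamp). Patients with no matching resource are absent.
#'
#' @inheritParams select_resources
#' @return data.frame with columns `patient_id`, `value`, `time`.
#' @export
extract_variable <- function(store, sel) {
  if (identical(sel$per_patient_policy, "all"))
    stop("per_patient_policy 'all' is not valid for extract_variable")
  res <- select_resources(store, sel)
  if (!length(res))
    return(data.frame(patient_id = character(), value = numeric(),
                      time = character()))
  if (identical(sel$resource_type, "Patient")) {
    field <- sel$field %||% stop("Patient selector needs a 'field' to extract")
    vals <- lapply(res, function(p)
      switch(field,
             gender = p$gender$code,
             age_years = p$age_years,
             deceased = p$deceased))
    return(data.frame(patient_id = vapply(res, `[[`, "", "id"),
                      value = unlist(vals),
                      time = NA_character_, stringsAsFactors = FALSE))
  }
  pid <- vapply(res, `[[`, "", "subject_ref")
  tms <- vapply(res, function(r) resource_time(r) %||% NA_character_, "")
  tnum <- as.numeric(parse_iso8601(tms))
  val <- lapply(res, function(r) {
    v <- r$value
    if (inherits(v, "quantity")) v$value
    else if (inherits(v, "coded_value")) v$code
    else if (is.null(v)) NA
    else v
  })
  pick <- tapply(seq_along(res), pid, function(ix) {
    if (length(ix) == 1L) return(ix)
    tt <- tnum[ix]
    tt[is.na(tt)] <- if (identical(sel$per_patient_policy, "latest"))
      -Inf else Inf
    ix[if (identical(sel$per_patient_policy, "latest"))
      which.max(tt) else which.min(tt)]
  })
  pick <- as.integer(pick)
  data.frame(patient_id = pid[pick], value = unlist(val[pick]),
             time = tms[pick], stringsAsFactors = FALSE)
}
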