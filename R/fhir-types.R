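#' Coded values and quantities
#'
#' `coded_value()` represents a code from a terminology system (LOINC,
#' ICD-10, SNOMED, CPT, AHFS, HL7 code systems, ...); two coded values are
#' equal iff their `(system, code)` pairs are equal. `quantity()` represents
#' a numeric value with a UCUM unit.
#'
#' @param system terminology-system identifier, e.g. `"http://loinc.org"`.
#' @param code code string within the system.
#' @param display optional human-readable label.
#' @return an object of class `coded_value`.
#' @examples
#' ph_code <- coded_value("http://loinc.org", "2744-1", "pH")
#' @export
coded_value <- function(system, code, display = NULL) {
  stopifnot(is_string(system), nzchar(system), is_string(code), nzchar(code))
  structure(list(system = system, code = code, display = display),
            class = "coded_value")
}

#' @rdname coded_value
#' @param value finite real number.
#' @param unit non-empty UCUM unit string (e.g. `"mmol/L"`, `"[pH]"`).
#' @export
quantity <- function(value, unit) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is_string(unit), nzchar(unit))
  structure(list(value = as.numeric(value), unit = unit), class = "quantity")
}

same_code <- function(a, b) {
  identical(a$system, b$system) && identical(a$code, b$code)
}

#' @export
print.coded_value <- function(x, ...) {
  cat(sprintf("<%s|%s>%s\n", x$system, x$code,
              if (!is.null(x$display)) paste0(" ", x$display) else ""))
  invisible(x)
}

FHIR_TYPES <- c("Patient", "Encounter", "Condition", "Observation",
                "MedicationAdministration", "ImagingStudy")

new_resource <- function(resource_type, id, fields) {
  r <- c(list(resource_type = resource_type, id = id), fields)
  class(r) <- c(paste0("fhir_", tolower(resource_type)), "fhir_resource")
  r
}

#' Construct FHIR resources (modeled subset)
#'
#' Constructors for the six resource types the platform models. All
#' identifiers are expected to be pseudonymized before a store is shared.
#' Timestamps are ISO 8601 strings. Age is carried as integer years rather
#' than a birth date, matching the de-identification posture.
#'
#' @param id resource identifier (string).
#' @param gender `coded_value` for administrative gender.
#' @param age_years integer age in years.
#' @param deceased logical vital status.
#' @return an object of class `fhir_resource`.
#' @examples
#' p <- fhir_patient("p1", gender_code("female"), 63, FALSE)
#' o <- fhir_observation("o1", "p1", loinc("2744-1", "pH"),
#'                       quantity(7.31, "[pH]"), "2023-02-01T08:30:00Z")
#' validate_resource(o)
#' @export
fhir_patient <- function(id, gender, age_years, deceased = FALSE) {
  new_resource("Patient", id, list(
    gender = gender, age_years = as.integer(age_years),
    deceased = isTRUE(deceased)))
}

#' @rdname fhir_patient
#' @param subject_ref pseudonymized id of the subject Patient.
#' @param code `coded_value` identifying what was measured/diagnosed/given.
#' @param value `quantity`, `coded_value` or logical (Observation only).
#' @param effective_time ISO 8601 timestamp.
#' @export
fhir_observation <- function(id, subject_ref, code, value, effective_time) {
  new_resource("Observation", id, list(
    subject_ref = subject_ref, code = code, value = value,
    effective_time = effective_time))
}

#' @rdname fhir_patient
#' @param period_start,period_end ISO 8601 encounter period bounds.
#' @export
fhir_encounter <- function(id, subject_ref, code, period_start,
                           period_end = NULL) {
  new_resource("Encounter", id, list(
    subject_ref = subject_ref, code = code,
    period_start = period_start, period_end = period_end))
}

#' @rdname fhir_patient
#' @export
fhir_condition <- function(id, subject_ref, code, effective_time = NULL) {
  new_resource("Condition", id, list(
    subject_ref = subject_ref, code = code, effective_time = effective_time))
}

#' @rdname fhir_patient
#' @export
fhir_medication_administration <- function(id, subject_ref, code,
                                           effective_time) {
  new_resource("MedicationAdministration", id, list(
    subject_ref = subject_ref, code = code, effective_time = effective_time))
}

#' @rdname fhir_patient
#' @param modality DICOM modality code string (e.g. `"CR"`, `"CT"`).
#' @param image_ref path/URI of the associated DICOM file.
#' @export
fhir_imaging_study <- function(id, subject_ref, modality, image_ref,
                               effective_time = NULL) {
  new_resource("ImagingStudy", id, list(
    subject_ref = subject_ref, modality = modality, image_ref = image_ref,
    effective_time = effective_time))
}

#' Convenience coders for common terminologies
#' @param code,display code and optional display string.
#' @export
loinc <- function(code, display = NULL)
  coded_value("http://loinc.org", code, display)

#' @rdname loinc
#' @export
icd10 <- function(code, display = NULL)
  coded_value("http://hl7.org/fhir/sid/icd-10", code, display)

#' @rdname loinc
#' @export
snomed <- function(code, display = NULL)
  coded_value("http://snomed.info/sct", code, display)

#' @rdname loinc
#' @export
gender_code <- function(code)
  coded_value("http://hl7.org/fhir/administrative-gender", code)

#' @export
print.fhir_resource <- function(x, ...) {
  cat(sprintf("<%s %s>", x$resource_type, x$id))
  if (!is.null(x$subject_ref)) cat(" subject:", x$subject_ref)
  if (!is.null(x$code)) cat(sprintf(" code:%s|%s", x$code$system, x$code$code))
  cat("\n")
  invisible(x)
}

ucum_common_units <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "ucum-common-units.txt",
                          package = "fedmed")
      cache <<- readLines(path, warn = FALSE)
      cache <<- cache[nzchar(cache) & !startsWith(cache, "#")]
    }
    cache
  }
})

#' Validate a FHIR resource against the modeled-subset invariants
#'
#' Checks required fields per resource type, ISO 8601 timestamps, non-empty
#' UCUM units, period ordering and value typing. Violations are returned as
#' data, not raised as errors.
#'
#' @param r a `fhir_resource`.
#' @return data.frame with columns `field` and `message`; zero rows iff the
#'   resource is valid.
#' @export
validate_resource <- function(r) {
  v <- list()
  bad <- function(field, message)
    v[[length(v) + 1L]] <<- data.frame(field = field, message = message,
                                       stringsAsFactors = FALSE)
  if (!inherits(r, "fhir_resource") ||
      !is_string(r$resource_type) || !(r$resource_type %in% FHIR_TYPES)) {
    return(data.frame(field = "resource_type",
                      message = "unsupported or missing resource type"))
  }
  if (!is_string(r$id) || !nzchar(r$id)) bad("id", "missing or empty id")
  ts_ok <- function(field) {
    t <- r[[field]]
    if (!is.null(t) && (!is_string(t) || !is_iso8601(t)))
      bad(field, "not a valid ISO 8601 timestamp")
  }
  if (r$resource_type == "Patient") {
    if (!inherits(r$gender, "coded_value")) bad("gender", "missing gender code")
    if (!is_count(r$age_years, min = 0)) bad("age_years", "missing/negative age")
    if (!is.logical(r$deceased)) bad("deceased", "deceased must be logical")
  } else {
    if (!is_string(r$subject_ref) || !nzchar(r$subject_ref %||% ""))
      bad("subject_ref", "missing subject reference")
  }
  if (r$resource_type %in% c("Observation", "Condition", "Encounter",
                             "MedicationAdministration")) {
    if (!inherits(r$code, "coded_value")) bad("code", "missing coded value")
  }
  if (r$resource_type == "Observation") {
    ts_ok("effective_time")
    if (is.null(r$effective_time)) bad("effective_time", "missing timestamp")
    val <- r$value
    if (inherits(val, "quantity")) {
      if (!nzchar(val$unit %||% "")) bad("value", "empty UCUM unit")
      if (!is.finite(val$value)) bad("value", "non-finite quantity")
    } else if (!inherits(val, "coded_value") &&
               !(is.logical(val) && length(val) == 1L)) {
      bad("value", "value must be quantity, coded_value or logical")
    }
  }
  if (r$resource_type == "Encounter") {
    ts_ok("period_start"); ts_ok("period_end")
    if (is.null(r$period_start)) bad("period_start", "missing period start")
    if (!is.null(r$period_start) && !is.null(r$period_end) &&
        is_iso8601(r$period_start %||% "") && is_iso8601(r$period_end %||% "") &&
        parse_iso8601(r$period_start) > parse_iso8601(r$period_end))
      bad("period", "period_start after period_end")
  }
  if (r$resource_type %in% c("Condition", "MedicationAdministration"))
    ts_ok("effective_time")
  if (r$resource_type == "MedicationAdministration" &&
      is.null(r$effective_time)) bad("effective_time", "missing timestamp")
  if (r$resource_type == "ImagingStudy") {
    if (!is_string(r$modality) || !nzchar(r$modality))
      bad("modality", "missing DICOM modality code")
    if (!is_string(r$image_ref)) bad("image_ref", "missing image reference")
    ts_ok("effective_time")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(), message = character())
}

#' Report observation units absent from the bundled UCUM common-unit list
#'
#' Unit membership is advisory (the bundled list covers common clinical
#' units, not all of UCUM), so unknown units are reported rather than
#' treated as invariant violations.
#'
#' @param resources list of `fhir_resource`.
#' @return data.frame of `(id, unit)` for quantity observations whose unit
#'   is not on the bundled list.
#' @export
check_ucum_units <- function(resources) {
  known <- ucum_common_units()
  rows <- lapply(resources, function(r) {
    if (identical(r$resource_type, "Observation") &&
        inherits(r$value, "quantity") && !(r$value$unit %in% known))
      data.frame(id = r$id, unit = r$value$unit, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows)
  else data.frame(id = character(), unit = character())
}
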