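AGE_EXT_URL <- "http://fedmed.example/fhir/StructureDefinition/age-years"
IMG_EXT_URL <- "http://fedmed.example/fhir/StructureDefinition/image-file"
DCM_SYSTEM <- "http://dicom.nema.org/resources/ontology/DCM"

coding_out <- function(cv) {
  out <- list(system = cv$system, code = cv$code)
  if (!is.null(cv$display)) out$display <- cv$display
  out
}

codeable_out <- function(cv) list(coding = list(coding_out(cv)))

coding_in <- function(x) {
  cd <- if (!is.null(x$coding)) x$coding[[1]] else x
  coded_value(cd$system, cd$code, cd$display)
}

subject_out <- function(id) list(reference = paste0("Patient/", id))
subject_in <- function(x) sub("^Patient/", "", x$reference)

# internal resource -> FHIR R4 JSON-able list (modeled subset)
resource_to_fhir <- function(r) {
  switch(r$resource_type,
    Patient = {
      out <- list(resourceType = "Patient", id = r$id,
                  gender = r$gender$code,
                  deceasedBoolean = r$deceased,
                  extension = list(list(url = AGE_EXT_URL,
                                        valueInteger = r$age_years)))
      out
    },
    Observation = {
      out <- list(resourceType = "Observation", id = r$id,
                  subject = subject_out(r$subject_ref),
                  code = codeable_out(r$code),
                  effectiveDateTime = r$effective_time)
      if (inherits(r$value, "quantity"))
        out$valueQuantity <- list(value = r$value$value, unit = r$value$unit)
      else if (inherits(r$value, "coded_value"))
        out$valueCodeableConcept <- codeable_out(r$value)
      else out$valueBoolean <- r$value
      out
    },
    Encounter = {
      out <- list(resourceType = "Encounter", id = r$id,
                  subject = subject_out(r$subject_ref),
                  class = coding_out(r$code),
                  period = c(list(start = r$period_start),
                             if (!is.null(r$period_end))
                               list(end = r$period_end)))
      out
    },
    Condition = {
      out <- list(resourceType = "Condition", id = r$id,
                  subject = subject_out(r$subject_ref),
                  code = codeable_out(r$code))
      if (!is.null(r$effective_time)) out$onsetDateTime <- r$effective_time
      out
    },
    MedicationAdministration = list(
      resourceType = "MedicationAdministration", id = r$id,
      subject = subject_out(r$subject_ref),
      medicationCodeableConcept = codeable_out(r$code),
      effectiveDateTime = r$effective_time),
    ImagingStudy = {
      out <- list(resourceType = "ImagingStudy", id = r$id,
                  subject = subject_out(r$subject_ref),
                  series = list(list(
                    uid = paste0(r$id, ".1"),
                    modality = list(system = DCM_SYSTEM, code = r$modality))),
                  extension = list(list(url = IMG_EXT_URL,
                                        valueString = r$image_ref)))
      if (!is.null(r$effective_time)) out$started <- r$effective_time
      out
    },
    stop("unsupported resource type: ", r$resource_type)
  )
}

fhir_to_resource <- function(x) {
  ty <- x$resourceType
  if (is.null(ty) || !(ty %in% FHIR_TYPES))
    stop("unsupported or missing resourceType")
  switch(ty,
    Patient = {
      age <- NULL
      for (e in x$extension %||% list())
        if (identical(e$url, AGE_EXT_URL)) age <- e$valueInteger
      fhir_patient(x$id, gender_code(x$gender), age,
                   isTRUE(x$deceasedBoolean))
    },
    Observation = {
      val <- if (!is.null(x$valueQuantity))
        quantity(x$valueQuantity$value, x$valueQuantity$unit)
      else if (!is.null(x$valueCodeableConcept))
        coding_in(x$valueCodeableConcept)
      else x$valueBoolean
      fhir_observation(x$id, subject_in(x$subject), coding_in(x$code),
                       val, x$effectiveDateTime)
    },
    Encounter = fhir_encounter(x$id, subject_in(x$subject),
                               coding_in(x$class),
                               x$period$start, x$period$end),
    Condition = fhir_condition(x$id, subject_in(x$subject),
                               coding_in(x$code), x$onsetDateTime),
    MedicationAdministration = fhir_medication_administration(
      x$id, subject_in(x$subject), coding_in(x$medicationCodeableConcept),
      x$effectiveDateTime),
    ImagingStudy = {
      img <- NULL
      for (e in x$extension %||% list())
        if (identical(e$url, IMG_EXT_URL)) img <- e$valueString
      fhir_imaging_study(x$id, subject_in(x$subject),
                         x$series[[1]]$modality$code, img, x$started)
    }
  )
}

#' Read FHIR resources from NDJSON
#'
#' One JSON object per line. Lines that fail to parse or violate the
#' modeled-subset invariants are skipped and reported (or abort the read in
#' strict mode).
#'
#' @param path NDJSON file path.
#' @param resource_type optional type tag; lines of other types are
#'   recorded as violations.
#' @param strict abort on the first bad line instead of skipping.
#' @return list with `resources` (in file order) and `violations`
#'   (data.frame of `line`, `message`).
#' @export
read_ndjson <- function(path, resource_type = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read NDJSON file: ", path)
  lines <- readLines(path, warn = FALSE)
  resources <- list()
  viol <- list()
  note <- function(i, msg) {
    if (strict) stop(sprintf("line %d: %s", i, msg))
    viol[[length(viol) + 1L]] <<- data.frame(line = i, message = msg)
  }
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) e)
    if (inherits(parsed, "error")) { note(i, "invalid JSON"); next }
    r <- tryCatch(fhir_to_resource(parsed), error = function(e) e)
    if (inherits(r, "error")) { note(i, conditionMessage(r)); next }
    if (!is.null(resource_type) &&
        !identical(r$resource_type, resource_type)) {
      note(i, sprintf("expected %s, found %s", resource_type,
                      r$resource_type))
      next
    }
    probs <- validate_resource(r)
    if (nrow(probs)) {
      note(i, paste(probs$message, collapse = "; "))
      next
    }
    resources[[length(resources) + 1L]] <- r
  }
  list(resources = resources,
       violations = if (length(viol)) do.call(rbind, viol)
                    else data.frame(line = integer(), message = character()))
}

#' Write FHIR resources as canonical NDJSON
#'
#' All resources are validated before any output is produced. Keys are
#' serialized in sorted order at every depth so identical resource sets
#' yield byte-identical files.
#'
#' @param resources list of `fhir_resource`.
#' @param path output file path.
#' @return number of lines written, invisibly.
#' @export
write_ndjson <- function(resources, path) {
  for (r in resources) {
    probs <- validate_resource(r)
    if (nrow(probs))
      stop(sprintf("invalid %s '%s': %s", r$resource_type, r$id,
                   paste(probs$message, collapse = "; ")))
  }
  lines <- vapply(resources,
                  function(r) as.character(canonical_json(resource_to_fhir(r))),
                  "")
  con <- file(path, open = "wb")  # byte-stable: LF endings everywhere
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(length(lines))
}
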