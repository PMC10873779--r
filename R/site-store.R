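#' Site-local resource store
#'
#' A `site_store` holds the de-identified resources of one hospital site.
#' It is the only structure patient-level operations ever see; everything
#' that leaves it is an aggregate.
#'
#' @param site_id site identifier string.
#' @param resources list of `fhir_resource` objects.
#' @return an object of class `site_store`.
#' @export
site_store <- function(site_id, resources = list()) {
  stopifnot(is_string(site_id), nzchar(site_id), is.list(resources))
  s <- structure(list(site_id = site_id, resources = resources),
                 class = "site_store")
  s
}

#' @rdname site_store
#' @param store a `site_store`.
#' @export
store_add <- function(store, resources) {
  stopifnot(inherits(store, "site_store"))
  if (inherits(resources, "fhir_resource")) resources <- list(resources)
  store$resources <- c(store$resources, resources)
  store
}

store_types <- function(store)
  vapply(store$resources, `[[`, "", "resource_type")

store_by_type <- function(store, type)
  store$resources[store_types(store) == type]

#' @rdname site_store
#' @export
store_count <- function(store) length(store$resources)

store_patients <- function(store) {
  ps <- store_by_type(store, "Patient")
  setNames(ps, vapply(ps, `[[`, "", "id"))
}

#' Check store-level invariants
#'
#' Ids must be unique within each resource type and every non-Patient
#' resource's `subject_ref` must resolve to a Patient in the same store.
#'
#' @param store a `site_store`.
#' @return data.frame of violations (zero rows iff the store is coherent).
#' @export
validate_store <- function(store) {
  stopifnot(inherits(store, "site_store"))
  out <- list()
  types <- store_types(store)
  ids <- vapply(store$resources, `[[`, "", "id")
  for (ty in unique(types)) {
    dup <- unique(ids[types == ty][duplicated(ids[types == ty])])
    for (d in dup)
      out[[length(out) + 1L]] <- data.frame(
        field = "id", message = sprintf("duplicate %s id '%s'", ty, d))
  }
  pat_ids <- ids[types == "Patient"]
  for (r in store$resources) {
    if (!identical(r$resource_type, "Patient") &&
        !(r$subject_ref %in% pat_ids))
      out[[length(out) + 1L]] <- data.frame(
        field = "subject_ref",
        message = sprintf("%s %s references unknown patient '%s'",
                          r$resource_type, r$id, r$subject_ref))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(field = character(), message = character())
}

#' @export
print.site_store <- function(x, ...) {
  tb <- table(store_types(x))
  cat(sprintf("<site_store '%s'> %d resources\n", x$site_id, store_count(x)))
  if (length(tb))
    cat(paste(sprintf("  %s: %d", names(tb), as.integer(tb)),
              collapse = "\n"), "\n")
  invisible(x)
}
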