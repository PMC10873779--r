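#' Generate a cryptographic secret
#'
#' Draws 512 bits from a cryptographically secure source and renders them
#' as a 128-character lowercase hexadecimal string. The default source
#' reads `/dev/urandom`; a deterministic test double can be supplied but
#' must be explicitly acknowledged as insecure.
#'
#' @param rng function `(n_bytes) -> raw vector` used as entropy source.
#' @param allow_insecure set `TRUE` to permit a non-default (e.g. seeded)
#'   source; refused otherwise.
#' @return a 128-character hex string.
#' @export
generate_secret <- function(rng = secure_random_bytes,
                            allow_insecure = FALSE) {
  if (!identical(rng, secure_random_bytes) && !isTRUE(allow_insecure))
    stop("non-default entropy source supplied without allow_insecure=TRUE; ",
         "secrets must come from a CSPRNG")
  bytes <- rng(64L)
  stopifnot(is.raw(bytes), length(bytes) == 64L)
  paste(sprintf("%02x", as.integer(bytes)), collapse = "")
}

#' @rdname generate_secret
#' @param n number of bytes to draw.
#' @export
secure_random_bytes <- function(n) {
  con <- file("/dev/urandom", open = "rb", raw = TRUE)
  on.exit(close(con))
  readBin(con, what = "raw", n = n)
}

#' Deterministic entropy double for tests (NOT cryptographically secure)
#' @param seed integer seed.
#' @return a `(n) -> raw` function producing a reproducible byte stream.
#' @export
insecure_seeded_bytes <- function(seed) {
  function(n) with_seed(seed, as.raw(sample.int(256L, n, replace = TRUE) - 1L))
}

is_secret <- function(x) is_string(x) && grepl("^[0-9a-f]{128}$", x)

#' Per-site secret material
#'
#' One 512-bit salt per site plus one 512-bit pepper per row key. Secrets
#' are site-local: they are never transmitted and must be excluded from any
#' export.
#'
#' @param row_keys character vector of raw row keys needing peppers.
#' @param rng entropy source, as in [generate_secret()].
#' @param allow_insecure as in [generate_secret()].
#' @return an object of class `site_secrets` with `salt` and `pepper_store`.
#' @export
site_secrets <- function(row_keys, rng = secure_random_bytes,
                         allow_insecure = FALSE) {
  stopifnot(is.character(row_keys), !anyDuplicated(row_keys))
  peppers <- vapply(row_keys, function(k)
    generate_secret(rng, allow_insecure), "")
  structure(list(salt = generate_secret(rng, allow_insecure),
                 pepper_store = setNames(peppers, row_keys)),
            class = "site_secrets")
}

#' @export
print.site_secrets <- function(x, ...) {
  cat(sprintf("<site_secrets> salt + %d peppers (values not shown)\n",
              length(x$pepper_store)))
  invisible(x)
}

#' Pseudonymize a key with PBKDF2-HMAC-SHA512
#'
#' Derives `hex(PBKDF2-HMAC-SHA512(password = key || pepper, salt = site
#' salt, 100 000 iterations, 64-byte key))`. Deterministic: the same
#' `(key, pepper, salt)` always yields the same digest, which is what
#' preserves referential integrity within a site, while differing salts
#' keep digest spaces of different sites disjoint.
#'
#' @param key raw row key (string).
#' @param pepper per-row 128-hex secret.
#' @param salt per-site 128-hex secret.
#' @param iterations PBKDF2 iteration count (default 100000).
#' @return 128-character hex digest.
#' @export
hash_key <- function(key, pepper, salt, iterations = 100000L) {
  stopifnot(is.character(key), all(nzchar(key) | key == ""))
  if (!is_secret(pepper)) stop("pepper must be a 128-char hex string")
  if (!is_secret(salt)) stop("salt must be a 128-char hex string")
  stopifnot(is_count(iterations))
  .pbkdf2_sha512(paste0(key, pepper), salt, as.integer(iterations), 64L)
}

#' Pseudonymize all identifiers in a store
#'
#' Replaces every resource id and subject reference with its peppered hash.
#' The same raw key always maps to the same digest within the site, so the
#' patient-resource reference graph is preserved up to relabeling.
#'
#' @param store a `site_store` with raw keys.
#' @param secrets a `site_secrets` whose pepper store covers every id.
#' @param iterations PBKDF2 iteration count.
#' @return the pseudonymized `site_store`.
#' @export
pseudonymize_store <- function(store, secrets, iterations = 100000L) {
  stopifnot(inherits(store, "site_store"), inherits(secrets, "site_secrets"))
  keys <- unique(vapply(store$resources, `[[`, "", "id"))
  missing <- setdiff(keys, names(secrets$pepper_store))
  if (length(missing))
    stop("no pepper for row key(s): ", paste(head(missing, 5), collapse = ", "))
  digest_of <- setNames(
    vapply(keys, function(k)
      hash_key(k, secrets$pepper_store[[k]], secrets$salt, iterations), ""),
    keys)
  store$resources <- lapply(store$resources, function(r) {
    r$id <- digest_of[[r$id]]
    if (!is.null(r$subject_ref)) {
      if (!(r$subject_ref %in% names(digest_of)))
        stop("subject_ref '", r$subject_ref, "' has no pepper/digest")
      r$subject_ref <- digest_of[[r$subject_ref]]
    }
    r
  })
  store
}

MASKED_CODE <- "MASKED"

#' Mask rare univariate characteristics
#'
#' Any categorical patient characteristic value (gender here) held by fewer
#' than `k` distinct patients is replaced by the reserved `MASKED` code;
#' any observation/condition/medication code present for fewer than `k`
#' distinct patients has all its resources removed from the store. Values
#' held by exactly `k` patients are retained.
#'
#' @param store a `site_store`.
#' @param k minimum distinct-patient count (default 5).
#' @return list with the masked `store` and a `report` data.frame
#'   `(kind, value, n_patients, action)`.
#' @export
mask_rare_characteristics <- function(store, k = 5L) {
  stopifnot(inherits(store, "site_store"), is_count(k, min = 2))
  report <- list()
  note <- function(kind, value, n, action)
    report[[length(report) + 1L]] <<- data.frame(
      kind = kind, value = value, n_patients = n, action = action,
      stringsAsFactors = FALSE)

  # categorical patient characteristics -> replace with MASKED code
  pats <- store_by_type(store, "Patient")
  genders <- vapply(pats, function(p) p$gender$code, "")
  tab <- table(genders)
  rare_gender <- names(tab)[tab < k & tab > 0]
  for (g in rare_gender) note("patient_characteristic", g,
                              as.integer(tab[[g]]), "masked")
  # coded resources -> drop whole series when rare
  coded_types <- c("Observation", "Condition", "MedicationAdministration")
  drop_keys <- character()
  for (ty in coded_types) {
    res <- store_by_type(store, ty)
    if (!length(res)) next
    key <- vapply(res, function(r) paste(r$code$system, r$code$code,
                                         sep = "|"), "")
    pid <- vapply(res, `[[`, "", "subject_ref")
    counts <- tapply(pid, key, function(p) length(unique(p)))
    rare <- names(counts)[counts < k]
    for (ky in rare) {
      note(paste0(tolower(ty), "_code"), ky, as.integer(counts[[ky]]),
           "removed")
      drop_keys <- c(drop_keys, paste0(ty, "::", ky))
    }
  }
  store$resources <- lapply(store$resources, function(r) {
    if (identical(r$resource_type, "Patient") &&
        r$gender$code %in% rare_gender) {
      r$gender <- coded_value(r$gender$system, MASKED_CODE)
      return(r)
    }
    if (r$resource_type %in% coded_types) {
      ky <- paste0(r$resource_type, "::", r$code$system, "|", r$code$code)
      if (ky %in% drop_keys) return(NULL)
    }
    r
  })
  store$resources <- store$resources[!vapply(store$resources, is.null,
                                             logical(1))]
  report <- if (length(report)) do.call(rbind, report)
    else data.frame(kind = character(), value = character(),
                    n_patients = integer(), action = character())
  list(store = store, report = report)
}

#' Write a masking report as CSV
#' @param report data.frame from [mask_rare_characteristics()].
#' @param path output path.
#' @export
write_masking_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
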