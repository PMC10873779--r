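test_that("secrets are 128-char hex from a guarded entropy source", {
  s1 <- generate_secret()
  s2 <- generate_secret()
  expect_match(s1, "^[0-9a-f]{128}$")
  expect_false(identical(s1, s2))
  # a deterministic double must be explicitly acknowledged as insecure
  expect_error(generate_secret(insecure_seeded_bytes(1)), "CSPRNG")
  d1 <- generate_secret(insecure_seeded_bytes(1), allow_insecure = TRUE)
  d2 <- generate_secret(insecure_seeded_bytes(1), allow_insecure = TRUE)
  expect_identical(d1, d2)
  expect_match(d1, "^[0-9a-f]{128}$")
})

test_that("hash_key reproduces frozen PBKDF2-HMAC-SHA512 golden digests", {
  # golden constants computed once with an independent PBKDF2
  # implementation (password = key || pepper, salt = site salt as ASCII,
  # 100000 iterations, 64-byte key)
  expect_identical(
    hash_key("patient-001", fix_pepper, fix_salt),
    paste0("1fc7cb07264c5c54b7f5d2d006d779d34e8fcf05f4a449979c7101595b88dd73",
           "3517525dcaf555c651c8521cb00e405ee7f04fd4e585c8b80539a5e2d0627339"))
  expect_identical(
    hash_key("obs-42", fix_pepper, fix_salt),
    paste0("ef532acc2d5b02935cfb59f0bb710d5278bc3ab5063a05d6b4729ee540ed01ba",
           "0c0e314b1aa68ffd4877c248e2f5cafda0bb4de990d5842ba833e3396f54c0a0"))
  # reduced-iteration vector, same oracle
  expect_identical(
    hash_key("patient-001", fix_pepper, fix_salt, iterations = 1000L),
    paste0("41fc751e8a2c2395e0ffeb069f3bd48cd619d4d92433041b02261f116188c508",
           "682accd05e3b328dd8bbf4a778c9c211faa0c6d93da918be36de26bef8e6412a"))
})

test_that("hash_key is deterministic, pepper/salt sensitive, format checked", {
  a <- hash_key("k", fix_pepper, fix_salt, iterations = 500L)
  expect_identical(a, hash_key("k", fix_pepper, fix_salt, iterations = 500L))
  other_pepper <- strrep("12", 64)
  expect_false(identical(a, hash_key("k", other_pepper, fix_salt,
                                     iterations = 500L)))
  expect_false(identical(a, hash_key("k", fix_pepper, strrep("ef", 64),
                                     iterations = 500L)))
  expect_error(hash_key("k", "deadbeef", fix_salt), "128-char")
})

test_that("hash_key has no collisions over a large random key corpus", {
  set.seed(4)
  keys <- unique(replicate(20000, paste(sample(letters, 8, TRUE),
                                        collapse = "")))
  digests <- hash_key(keys, fix_pepper, fix_salt, iterations = 2L)
  expect_false(anyDuplicated(digests) > 0)
})

test_that("pseudonymize_store preserves referential integrity", {
  store <- site_store("s", list(
    fhir_patient("p1", gender_code("female"), 63),
    fhir_observation("o1", "p1", loinc("2744-1"), quantity(7.3, "[pH]"),
                     fix_time(1)),
    fhir_observation("o2", "p1", loinc("2744-1"), quantity(7.4, "[pH]"),
                     fix_time(2))))
  secrets <- site_secrets(c("p1", "o1", "o2"),
                          insecure_seeded_bytes(7), allow_insecure = TRUE)
  out <- pseudonymize_store(store, secrets, iterations = 100L)
  ids <- vapply(out$resources, `[[`, "", "id")
  expect_false(any(ids %in% c("p1", "o1", "o2")))
  expect_match(ids, "^[0-9a-f]{128}$")
  pat_id <- out$resources[[1]]$id
  expect_identical(out$resources[[2]]$subject_ref, pat_id)
  expect_identical(out$resources[[3]]$subject_ref, pat_id)
  expect_equal(nrow(validate_store(out)), 0L)

  # reference graph is preserved up to relabeling: same shape before/after
  graph_of <- function(s) {
    e <- vapply(s$resources, function(r)
      paste(r$resource_type, !is.null(r$subject_ref)), "")
    sort(e)
  }
  expect_identical(graph_of(store), graph_of(out))

  # two sites with different salts produce disjoint digest sets
  secrets2 <- site_secrets(c("p1", "o1", "o2"),
                           insecure_seeded_bytes(8), allow_insecure = TRUE)
  out2 <- pseudonymize_store(store, secrets2, iterations = 100L)
  expect_length(intersect(vapply(out$resources, `[[`, "", "id"),
                          vapply(out2$resources, `[[`, "", "id")), 0L)

  # missing pepper is an integrity error
  expect_error(pseudonymize_store(store, site_secrets(
    c("p1", "o1"), insecure_seeded_bytes(9), allow_insecure = TRUE),
    iterations = 100L), "pepper")

  empty <- pseudonymize_store(site_store("s"), secrets, iterations = 100L)
  expect_equal(store_count(empty), 0L)
})

test_that("rare characteristics are masked at the k-threshold boundary", {
  # 4 patients with a rare diagnosis code, 5 with a retained one
  res <- list()
  for (i in 1:9) {
    pid <- sprintf("p%d", i)
    res[[length(res) + 1L]] <- fhir_patient(pid, gender_code("female"), 60)
    res[[length(res) + 1L]] <- fhir_condition(
      sprintf("c%d", i), pid,
      if (i <= 4) icd10("J96.0", "resp failure") else icd10("U07.1"),
      fix_time(i))
  }
  store <- site_store("s", res)
  out <- mask_rare_characteristics(store, k = 5L)
  codes <- vapply(fedmed:::store_by_type(out$store, "Condition"),
                  function(r) r$code$code, "")
  expect_false("J96.0" %in% codes)       # 4 < 5 -> removed
  expect_equal(sum(codes == "U07.1"), 5) # exactly 5 -> retained
  expect_equal(out$report$n_patients, 4L)
  expect_equal(out$report$action, "removed")
})

test_that("rare observation series are dropped wholesale and reported", {
  res <- list()
  for (i in 1:8) {
    pid <- sprintf("p%d", i)
    res[[length(res) + 1L]] <- fhir_patient(pid, gender_code("female"), 60)
    res[[length(res) + 1L]] <- fhir_observation(
      sprintf("o%d", i), pid, loinc("2744-1"), quantity(7.3, "[pH]"),
      fix_time(i))
  }
  # lactate observed in only 3 patients (two observations each)
  for (i in 1:3) for (j in 1:2)
    res[[length(res) + 1L]] <- fhir_observation(
      sprintf("lac%d-%d", i, j), sprintf("p%d", i),
      loinc("2524-7", "lactate"), quantity(2.0, "mmol/L"), fix_time(j))
  out <- mask_rare_characteristics(site_store("s", res), k = 5L)
  codes <- vapply(fedmed:::store_by_type(out$store, "Observation"),
                  function(r) r$code$code, "")
  expect_false("2524-7" %in% codes)
  expect_equal(sum(codes == "2744-1"), 8L)
  lac <- out$report[out$report$value == "http://loinc.org|2524-7", ]
  expect_equal(lac$n_patients, 3L)
})

test_that("masking leaves no retained value with patient count in (0, k)", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(6:25, 1)
    k <- sample(2:6, 1)
    res <- list()
    for (i in seq_len(n)) {
      pid <- sprintf("p%d", i)
      res[[length(res) + 1L]] <- fhir_patient(
        pid, gender_code(sample(c("female", "male", "other"), 1,
                                prob = c(.45, .45, .1))), 60)
      for (code in sample(c("A", "B", "C", "D"), sample(0:2, 1)))
        res[[length(res) + 1L]] <- fhir_condition(
          paste0(pid, "-", code), pid, icd10(code), fix_time(1))
    }
    out <- mask_rare_characteristics(site_store("s", res), k = k)
    conds <- fedmed:::store_by_type(out$store, "Condition")
    if (length(conds)) {
      counts <- tapply(vapply(conds, `[[`, "", "subject_ref"),
                       vapply(conds, function(r) r$code$code, ""),
                       function(p) length(unique(p)))
      expect_true(all(counts == 0 | counts >= k))
    }
    pats <- fedmed:::store_by_type(out$store, "Patient")
    gtab <- table(vapply(pats, function(p) p$gender$code, ""))
    gtab <- gtab[names(gtab) != "MASKED"]
    expect_true(all(gtab == 0 | gtab >= k))
  }
})

test_that("DICOM whitelist scrubbing drops sensitive tags, keeps pixels", {
  px <- matrix(sample(0:255, 24 * 24, TRUE), 24)
  ds <- dicom_create(px, extra_elements = list(
    "0010,0010" = list(value = "DOE^JANE", vr = "PN"),
    "0010,0020" = list(value = "MRN-123", vr = "LO"),
    "0008,0080" = list(value = "General Hospital", vr = "LO")))
  wl <- dicom_whitelist()
  out <- deidentify_dicom(ds, wl)
  # tag-set containment checked by independent enumeration
  expect_true(all(names(out$elements) %in% wl$allowed_tags))
  expect_false(any(c("0010,0010", "0010,0020", "0008,0080") %in%
                     names(out$elements)))
  expect_identical(out$elements[["7FE0,0010"]]$value,
                   ds$elements[["7FE0,0010"]]$value)
  expect_identical(dicom_pixels(out), px)
  # idempotent
  expect_identical(deidentify_dicom(out, wl), out)
  # identifying tags can never be whitelisted
  expect_error(dicom_whitelist(c("0008,0060", "0010,0010")), "never")
})

test_that("DICOM Part 10 files round-trip and are readable by pydicom", {
  px <- matrix(sample(0:255, 32 * 32, TRUE), 32)
  ds <- dicom_create(px)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(ds, f)
  back <- read_dicom(f)
  expect_identical(dicom_pixels(back), px)
  expect_identical(back$elements[["0008,0060"]]$value, "CR")
  expect_error(read_dicom(withr::local_tempfile(fileext = ".txt",
                                                lines = "not dicom")),
               "not a DICOM")
  # independent reader oracle (pydicom), if python is available
  py <- Sys.which("python")
  if (nzchar(py)) {
    out <- suppressWarnings(system2(py, c("-c", shQuote(sprintf(
      "import pydicom; d = pydicom.dcmread('%s'); print(d.Rows, d.Columns, int(d.pixel_array.sum()))",
      f))), stdout = TRUE, stderr = FALSE))
    if (length(out) == 1 && !is.null(attr(out, "status")) == FALSE)
      expect_identical(out, sprintf("32 32 %d", sum(px)))
  }
})
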