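test_that("resource validation enforces the modeled-subset invariants", {
  ok <- fhir_observation("o1", "p1", loinc("2744-1", "pH"),
                         quantity(7.31, "mmol/L"),
                         "2021-03-01T10:00:00Z")
  expect_equal(nrow(validate_resource(ok)), 0L)

  bad_ts <- fhir_observation("o2", "p1", loinc("2744-1"),
                             quantity(7.31, "[pH]"), "03/01/2021")
  v <- validate_resource(bad_ts)
  expect_equal(nrow(v), 1L)
  expect_equal(v$field, "effective_time")

  bad_period <- fhir_encounter("e1", "p1",
                               coded_value("http://hl7.org/enc", "IMP"),
                               period_start = "2023-02-02T00:00:00Z",
                               period_end = "2023-02-01T00:00:00Z")
  expect_true("period" %in% validate_resource(bad_period)$field)

  # empty UCUM unit cannot even be constructed; a hand-built one is caught
  raw <- fhir_observation("o3", "p1", loinc("2744-1"),
                          quantity(7.31, "[pH]"), fix_time(1))
  raw$value$unit <- ""
  expect_true(any(grepl("UCUM", validate_resource(raw)$message)))
})

test_that("unknown units are advisory, not violations", {
  known <- fhir_observation("o1", "p1", loinc("2744-1"),
                            quantity(7.3, "[pH]"), fix_time(1))
  odd <- fhir_observation("o2", "p1", loinc("999-9"),
                          quantity(1, "furlong"), fix_time(1))
  expect_equal(nrow(validate_resource(odd)), 0L)
  rep <- check_ucum_units(list(known, odd))
  expect_equal(rep$unit, "furlong")
})

test_that("NDJSON writing is canonical and reading round-trips", {
  store <- make_ph_store(4)
  f1 <- withr::local_tempfile(fileext = ".ndjson")
  f2 <- withr::local_tempfile(fileext = ".ndjson")
  n <- write_ndjson(store$resources, f1)
  expect_equal(n, store_count(store))
  expect_identical(write_ndjson(store$resources, f2), n)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  rd <- read_ndjson(f1)
  expect_equal(nrow(rd$violations), 0L)
  expect_equal(length(rd$resources), n)
  # round-trip preserves the resource multiset (compare canonical dumps)
  canon <- function(rs) sort(vapply(rs, function(r)
    as.character(fedmed:::canonical_json(fedmed:::resource_to_fhir(r))), ""))
  expect_identical(canon(rd$resources), canon(store$resources))

  empty <- withr::local_tempfile(fileext = ".ndjson")
  expect_equal(write_ndjson(list(), empty), 0L)
  expect_length(read_ndjson(empty)$resources, 0L)
})

test_that("bad NDJSON lines are skipped and reported, strict mode aborts", {
  f <- withr::local_tempfile(fileext = ".ndjson")
  store <- make_ph_store(2)
  write_ndjson(store$resources, f)
  cat("this is not json\n", file = f, append = TRUE)
  rd <- read_ndjson(f)
  expect_length(rd$resources, store_count(store))
  expect_equal(nrow(rd$violations), 1L)
  expect_error(read_ndjson(f, strict = TRUE), "line")
  expect_error(read_ndjson(tempfile()), "cannot read")
})

test_that("selector filters compose conjunctively and respect half-open windows", {
  store <- make_ph_store(10)
  all_obs <- select_resources(store, ph_selector())
  expect_length(all_obs, 10L)

  # code filter keeps only matching codes
  store2 <- store_add(store, fhir_observation(
    "x1", "p01", loinc("2345-7", "glucose"), quantity(5.4, "mmol/L"),
    fix_time(3)))
  expect_length(select_resources(store2, ph_selector()), 10L)

  # record exactly at the window end is excluded
  t_end <- "2023-01-01T10:00:00Z"
  store3 <- site_store("s", list(
    fhir_patient("p1", gender_code("female"), 60),
    fhir_observation("o1", "p1", loinc("2744-1"), quantity(7.3, "[pH]"),
                     "2023-01-01T09:59:59Z"),
    fhir_observation("o2", "p1", loinc("2744-1"), quantity(7.4, "[pH]"),
                     t_end)))
  sel <- ph_selector(time_window = c("2023-01-01T00:00:00Z", t_end))
  hits <- select_resources(store3, sel)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$id, "o1")

  # conjunction equals intersection of single-filter selections
  sel_code <- ph_selector()
  sel_val <- resource_selector("Observation", value_range = c(7.32, 7.40))
  sel_both <- ph_selector(value_range = c(7.32, 7.40))
  ids <- function(rs) sort(vapply(rs, `[[`, "", "id"))
  expect_identical(
    ids(select_resources(store, sel_both)),
    intersect(ids(select_resources(store, sel_code)),
              ids(select_resources(store, sel_val))))

  # idempotence: re-selecting from the selected subset changes nothing
  sub <- site_store("s", select_resources(store, sel_val))
  expect_identical(ids(select_resources(sub, sel_val)),
                   ids(select_resources(store, sel_val)))
})

test_that("extract_variable reduces per patient by time policy", {
  store <- site_store("s", list(
    fhir_patient("p1", gender_code("female"), 70),
    fhir_observation("o1", "p1", loinc("2744-1"), quantity(7.2, "[pH]"),
                     fix_time(1)),
    fhir_observation("o2", "p1", loinc("2744-1"), quantity(7.4, "[pH]"),
                     fix_time(2))))
  latest <- extract_variable(store, ph_selector(per_patient_policy = "latest"))
  expect_equal(latest$value, 7.4)
  earliest <- extract_variable(store,
                               ph_selector(per_patient_policy = "earliest"))
  expect_equal(earliest$value, 7.2)

  # patient with no matching observation is absent
  store <- store_add(store, fhir_patient("p2", gender_code("male"), 60))
  tab <- extract_variable(store, ph_selector())
  expect_identical(tab$patient_id, "p1")

  expect_error(extract_variable(store, ph_selector(per_patient_policy = "all")),
               "not valid")
})

test_that("earliest-policy extraction matches a brute-force per-patient scan", {
  store <- make_ph_store(3, obs_per_patient = 2L)
  sel <- ph_selector(per_patient_policy = "earliest")
  tab <- extract_variable(store, sel)
  expect_equal(nrow(tab), 3L)
  # brute force: scan every observation, keep min-time per patient
  obs <- fedmed:::store_by_type(store, "Observation")
  brute <- new.env()
  for (o in obs) {
    t <- as.numeric(parse_iso8601(o$effective_time))
    prev <- brute[[o$subject_ref]]
    if (is.null(prev) || t < prev$t)
      brute[[o$subject_ref]] <- list(t = t, v = o$value$value)
  }
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$value[i], brute[[tab$patient_id[i]]]$v)
})

test_that("store invariants catch duplicate ids and dangling references", {
  good <- make_ph_store(3)
  expect_equal(nrow(validate_store(good)), 0L)
  dup <- store_add(good, fhir_patient("p01", gender_code("male"), 40))
  expect_true(any(grepl("duplicate", validate_store(dup)$message)))
  dangling <- store_add(good, fhir_observation(
    "ox", "ghost", loinc("2744-1"), quantity(7.0, "[pH]"), fix_time(1)))
  expect_true(any(grepl("unknown patient", validate_store(dangling)$message)))
})
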