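# in-code fixtures shared across test files

fix_time <- function(day, hour = 10L)
  sprintf("2023-01-%02dT%02d:00:00Z", day, hour)

# a small coherent store: n patients, each with one-or-more pH observations
make_ph_store <- function(n = 6L, site_id = "site-a", ph = NULL,
                          obs_per_patient = 1L) {
  res <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("p%02d", i)
    res[[length(res) + 1L]] <- fhir_patient(
      pid, gender_code(if (i %% 2) "female" else "male"), 50 + i,
      deceased = FALSE)
    for (j in seq_len(obs_per_patient)) {
      val <- if (is.null(ph)) 7.3 + 0.01 * i + 0.001 * j else ph[i]
      res[[length(res) + 1L]] <- fhir_observation(
        sprintf("%s-o%d", pid, j), pid, loinc("2744-1", "pH"),
        quantity(val, "[pH]"), fix_time(j, hour = (8L + i) %% 24L))
    }
  }
  site_store(site_id, res)
}

# store whose observation values are exactly `values` (one per patient)
value_store <- function(values, site_id = "s") {
  res <- list()
  for (i in seq_along(values)) {
    pid <- sprintf("p%03d", i)
    res[[length(res) + 1L]] <- fhir_patient(pid, gender_code("female"), 60)
    res[[length(res) + 1L]] <- fhir_observation(
      paste0(pid, "-o"), pid, loinc("2744-1"), quantity(values[i], "[pH]"),
      fix_time(1L + (i %% 27L)))
  }
  site_store(site_id, res)
}

ph_selector <- function(...) {
  resource_selector("Observation", code_filter = loinc("2744-1"), ...)
}

tiny_model_spec <- function()
  model_spec(tabular_input_dim = 2L, image_input_shape = c(8L, 8L, 1L),
             conv_filters = 2L, image_dense = 3L, tabular_units = 3L,
             merge_units = 2L)

random_tab_data <- function(n, d = 3L, seed = 1L) {
  set.seed(seed)
  list(xtab = matrix(rnorm(n * d), n, d), ximg = NULL,
       y = rbinom(n, 1, 0.4))
}

# fixture secrets (valid format, deterministic)
fix_pepper <- strrep("ab", 64)
fix_salt <- strrep("cd", 64)
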