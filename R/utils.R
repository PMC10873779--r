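`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse an ISO 8601 timestamp
#'
#' Accepts `YYYY-MM-DD` dates and `YYYY-MM-DDThh:mm:ss` date-times with an
#' optional fractional second and an optional `Z` or `+hh:mm` offset.
#' Anything else (including `03/01/2021`-style dates) is rejected.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` (UTC); `NA` where the input is not valid ISO 8601.
#' @export
parse_iso8601 <- function(x) {
  re <- paste0(
    "^\\d{4}-\\d{2}-\\d{2}",
    "(T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|[+-]\\d{2}:?\\d{2})?)?$"
  )
  out <- rep(as.POSIXct(NA), length(x))
  ok <- !is.na(x) & grepl(re, x)
  if (any(ok)) {
    xs <- x[ok]
    # normalize: date-only -> midnight UTC; trailing Z -> +0000
    xs <- ifelse(grepl("T", xs), xs, paste0(xs, "T00:00:00Z"))
    xs <- sub("Z$", "+0000", xs)
    xs <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", xs)
    has_off <- grepl("[+-]\\d{4}$", xs)
    xs[!has_off] <- paste0(xs[!has_off], "+0000")
    xs <- sub("(\\.\\d+)", "", xs)  # drop fractional seconds
    val <- as.POSIXct(xs, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
    out[ok] <- val
    ok[ok] <- !is.na(val)
  }
  out[!ok] <- NA
  out
}

is_iso8601 <- function(x) !is.na(parse_iso8601(x))

format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

# Canonical JSON: named lists serialized with keys in sorted order at every
# depth, scalars unboxed, so identical objects give byte-identical lines.
sort_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    x <- lapply(x, sort_keys)
  }
  x
}

canonical_json <- function(x) {
  jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}

# deterministic, seed-local RNG evaluation
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
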