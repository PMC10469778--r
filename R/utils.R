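assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    stop(name, " must be a finite scalar in ",
         if (strict) "(" else "[", lower, ", ", upper,
         if (strict) ")" else "]", call. = FALSE)
  }
  invisible(x)
}

# md5 of a canonical serialization; used for report provenance
config_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# half-open [start, end) overlap test for interval pairs (vectorised over b)
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  any(a_start < b_end & b_start < a_end)
}
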