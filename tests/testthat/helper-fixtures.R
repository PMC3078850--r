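# Small in-code fixtures shared across test files.

# write a demography CSV and load it through the public reader
demog_from_df <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  load_demography(path)
}

# a minimal two-cell demography: everyone aged [40, 50), both sexes
tiny_demog <- function() {
  demog_from_df(data.frame(
    age_lo = c(40L, 40L), age_hi = c(50L, 50L),
    sex = c("F", "M"), proportion = c(0.5, 0.5)
  ))
}

# a flat incidence surface: p0 rises linearly to `top` by age 89
flat_incidence <- function(top = 0.1, min_age = 40L, max_age = 89L) {
  ages <- min_age:max_age
  p0 <- top * (ages - min_age) / (max_age - min_age)
  validate_incidence_for_test(data.frame(
    sex = rep(c("F", "M"), each = length(ages)),
    age = rep(ages, 2), p0 = rep(p0, 2)
  ))
}

validate_incidence_for_test <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  load_incidence(path)
}

# packaged inputs, loaded once per test run
pkg_demog <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- load_demography("canada2006")
    value
  }
})

pkg_baseline <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- default_baseline(demog = pkg_demog())
    value
  }
})

# a deterministic cohort data.frame realizing exact 2x2 (x stratum) counts
cohort_from_counts <- function(counts) {
  # counts: data.frame with columns carrier, event, n and optional age/sex/statin
  idx <- rep(seq_len(nrow(counts)), counts$n)
  out <- counts[idx, setdiff(names(counts), "n"), drop = FALSE]
  rownames(out) <- NULL
  out
}
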