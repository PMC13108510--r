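# Small shared fixtures, built once per test run.

tiny_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, n_elements = 60,
                                 n_regions = 40, n_frames = 120,
                                 seed = 42L), list(...))
  do.call(cohort_config, args)
}

# one default-condition subject reused across read-only tests
fixture_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_subject(cohort_config(n_frames = 250, seed = 7L), 1)
    }
    cache
  }
})

raw_fc <- function(subject) {
  es <- subject$echo_series
  x <- bandpass(se_view(es), tr_s = es$tr_s)
  fc_matrix(parcellate(x))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
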