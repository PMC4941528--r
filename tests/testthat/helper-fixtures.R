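# Shared fixtures: all synthetic, generated in code at test time.

# Small population for fast unit tests.
tiny_config <- function(seed = NULL, ...) {
  population_config(n_male = 4, n_female = 4, n_juv_male = 2, n_juv_female = 1,
                    prints_per_subject = c(4, 6), seed = seed, ...)
}

# Full-size reference table (~490 prints from 41 subjects), cached per session.
reference_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- population_config(seed = 1101)
      cache <<- generate_footprints(generate_population(cfg), cfg)
    }
    cache
  }
})

walk_template <- function() default_template_library()$human_walk

zero_profile <- function() stats::setNames(rep(0, 14), depth_regions())

# Random symmetric positive-definite matrix via A'A + eps*I.
random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}
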