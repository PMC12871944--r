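# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

small_cohort <- function() {
  memo("small_cohort", generate_cohort(cohort_config(n_users = 12, seed = 7)))
}

small_features <- function() {
  memo("small_features", {
    cumulative_median_aggregate(assemble_daily_features(small_cohort()))
  })
}

# A toy GPS track builder
toy_track <- function(hour, lat, lon) tibble::tibble(hour = hour, lat = lat,
                                                     lon = lon)

# Tiny deterministic embedding fixture: users with well-separated signatures
# plus day noise.
separable_features <- function(n_users = 10, n_days = 8, noise = 0.3,
                               d = 6, seed = 99) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(n_users * d, sd = 2), n_users, d)
    rows <- do.call(rbind, lapply(seq_len(n_users), function(u) {
      centers[rep(u, n_days), ] + matrix(rnorm(n_days * d, sd = noise),
                                         n_days, d)
    }))
    colnames(rows) <- paste0("f", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(user_id = rep(sprintf("u%02d", seq_len(n_users)),
                                   each = n_days),
                     day = rep(seq_len(n_days), n_users)),
      tibble::as_tibble(rows)
    )
  })
}
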