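test_that("spearman table matches closed forms and a midrank oracle", {
  uf <- tibble::tibble(user_id = sprintf("u%d", 1:8),
                       up = 1:8, down = 8:1,
                       tied = c(1, 1, 2, 2, 3, 3, 4, 4),
                       flat = rep(5, 8))
  oc <- tibble::tibble(user_id = sprintf("u%d", 1:8),
                       sdq_total = c(2, 4, 7, 9, 12, 15, 18, 21),
                       sci_total = 32 - (1:8), ed15_total = (1:8) / 2,
                       si_frequency = rep(0:1, 4))
  tab <- spearman_table(uf, oc)
  expect_equal(tab$rho[tab$feature == "up" & tab$outcome == "sdq"], 1)
  expect_equal(tab$rho[tab$feature == "down" & tab$outcome == "sdq"], -1)
  expect_true(is.na(tab$rho[tab$feature == "flat" & tab$outcome == "sdq"]))
  expect_equal(tab$note[tab$feature == "flat" & tab$outcome == "sdq"],
               "constant")
  # midrank brute-force oracle for tied data
  r1 <- rank(uf$tied)
  r2 <- rank(oc$sdq_total)
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(tab$rho[tab$feature == "tied" & tab$outcome == "sdq"],
               oracle, tolerance = 1e-12)
  # BH is applied within outcome and keeps p_adj >= p
  ok <- !is.na(tab$p)
  expect_true(all(tab$p_adj[ok] >= tab$p[ok] - 1e-12))
})

test_that("group difference tests match the closed-form Welch oracle", {
  withr::with_seed(111, {
    uf <- tibble::tibble(user_id = sprintf("u%d", 1:20),
                         f_sep = c(rnorm(10, 2), rnorm(10, 0)),
                         f_null = rnorm(20))
    labels <- rep(c(TRUE, FALSE), each = 10)
    out <- group_difference_tests(uf, labels)
    # closed-form Welch on standardized values
    z <- (uf$f_sep - mean(uf$f_sep)) / sd(uf$f_sep)
    hi <- z[labels]; lo <- z[!labels]
    se <- sqrt(var(hi) / 10 + var(lo) / 10)
    t_oracle <- (mean(hi) - mean(lo)) / se
    df <- se^4 / ((var(hi) / 10)^2 / 9 + (var(lo) / 10)^2 / 9)
    p_oracle <- 2 * pt(abs(t_oracle), df, lower.tail = FALSE)
    row <- out[out$feature == "f_sep", ]
    expect_equal(row$t, t_oracle, tolerance = 1e-12)
    expect_equal(row$p, p_oracle, tolerance = 1e-12)
    expect_equal(row$direction, "higher_in_high_risk")
  })
  # identical groups: t = 0, p = 1
  uf2 <- tibble::tibble(user_id = sprintf("u%d", 1:8), f = rep(2, 8))
  out2 <- group_difference_tests(uf2, rep(c(TRUE, FALSE), 4))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  expect_error(group_difference_tests(uf2, c(TRUE, rep(FALSE, 7))),
               class = "phenosense_validation_error")
})

test_that("BH adjustment matches the step-up arithmetic", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
  # monotone in rank order
  withr::with_seed(113, {
    pv <- runif(20)
    adj <- p.adjust(pv, "BH")
    ord <- order(pv)
    expect_false(is.unsorted(adj[ord]))
  })
})

test_that("sampling Shapley satisfies additivity and linear-model exactness", {
  # constant model: zero attributions
  f_const <- function(X) rep(2.5, nrow(X))
  B <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("x", 1:5)))
  X <- matrix(rnorm(15), 3, 5, dimnames = list(NULL, paste0("x", 1:5)))
  at <- shap_attributions(f_const, B, X, n_perm = 2, seed = 1)
  expect_true(all(abs(at) < 1e-12))
  # single-feature linear logit: attribution = beta * (x - mean(background))
  f_lin <- function(Xm) 3 * Xm[, 2]
  at2 <- shap_attributions(f_lin, B, X, n_perm = 2, seed = 2)
  expect_equal(at2[, 2], 3 * (X[, 2] - mean(B[, 2])), tolerance = 1e-10)
  expect_true(all(abs(at2[, -2]) < 1e-10))
  # additivity: rows sum to f(x) - mean_b f(b)
  f_nl <- function(Xm) Xm[, 1] * Xm[, 3] + sin(Xm[, 2]) - 0.5 * Xm[, 4]^2
  at3 <- shap_attributions(f_nl, B, X, n_perm = 3, seed = 3)
  expect_equal(rowSums(at3), f_nl(X) - mean(f_nl(B)), tolerance = 1e-2)
})

test_that("sampling Shapley approximates exhaustive Shapley on a 5-feature toy", {
  withr::with_seed(117, {
    d <- 5
    W1 <- matrix(rnorm(d * 3), d, 3)
    f <- function(Xm) {
      H <- pmax(Xm %*% W1, 0)
      as.numeric(H %*% c(1, -1, 0.5))
    }
    B <- matrix(rnorm(6 * d), 6, d, dimnames = list(NULL, paste0("x", 1:d)))
    X <- matrix(rnorm(2 * d), 2, d, dimnames = list(NULL, paste0("x", 1:d)))
    # exhaustive Shapley with background-expectation value function
    exact_shap <- function(x) {
      phi <- numeric(d)
      val <- function(S) {
        Xs <- B
        Xs[, S] <- matrix(x[S], nrow(B), length(S), byrow = TRUE)
        mean(f(Xs))
      }
      for (j in 1:d) {
        others <- setdiff(1:d, j)
        for (k in 0:length(others)) {
          combs <- utils::combn(others, k)
          if (k == 0) combs <- matrix(numeric(0), 0, 1)
          for (ci in seq_len(ncol(combs))) {
            S <- combs[, ci]
            wgt <- factorial(k) * factorial(d - k - 1) / factorial(d)
            phi[j] <- phi[j] + wgt * (val(c(S, j)) - val(S))
          }
        }
      }
      phi
    }
    approx <- shap_attributions(f, B, X, n_perm = 300, seed = 5)
    for (i in 1:2) {
      exact <- exact_shap(X[i, ])
      scale_ref <- max(abs(exact))
      expect_lt(max(abs(approx[i, ] - exact)), 0.05 * max(scale_ref, 1))
    }
  })
})

test_that("importances aggregate by sensor with conservation", {
  reg <- feature_registry()
  items <- active_item_registry()
  cols <- c(items$name, reg$name)
  at <- matrix(0, 4, length(cols), dimnames = list(NULL, cols))
  at[, "loc_entropy"] <- 2
  at[, "loc_gyration"] <- c(-1, 1, -1, 1)
  at[, "negative_thinking"] <- 0.5
  imp <- aggregate_importance_by_sensor(at)
  expect_equal(imp$term[1], "location")
  loc_members <- reg$name[reg$category == "location"]
  expect_equal(imp$importance[imp$term == "location"],
               sum(colMeans(abs(at))[loc_members]))
  expect_equal(imp$importance[imp$term == "negative_thinking"], 0.5)
  # all-zero attributions -> all-zero importances
  imp0 <- aggregate_importance_by_sensor(at * 0)
  expect_true(all(imp0$importance == 0))
  # unregistered columns error
  bad <- at
  colnames(bad)[1] <- "mystery"
  expect_error(aggregate_importance_by_sensor(bad),
               class = "phenosense_validation_error")
})

test_that("published anchor-feature correlation signs are recovered", {
  # the nine passive association anchors and their published directions,
  # checked on full-coverage Android cohorts across seeds
  anchors <- list(
    c("noise_max_day", "sdq_total", -1),
    c("loc_mean_lat", "si_frequency", +1),
    c("app_time_entertainment", "si_frequency", +1),
    c("light_median_night", "sci_total", -1),
    c("loc_mean_lon", "sci_total", -1),
    c("noise_sd_day", "si_frequency", -1),
    c("app_time_median_day", "si_frequency", +1),
    c("noise_mean_night", "ed15_total", +1),
    c("app_events_night", "ed15_total", +1)
  )
  correct <- 0L
  total <- 0L
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(
      n_users = 120, seed = 9000 + s, ios_fraction = 0,
      zero_sensor_fraction = 0, active_retention_final = 1,
      sensor_optin_rates = setNames(rep(1, 8),
                                    names(sensor_optin_defaults()))))
    um <- user_feature_medians(assemble_daily_features(coh))
    oc <- coh$outcomes[match(um$user_id, coh$outcomes$user_id), ]
    for (an in anchors) {
      r <- suppressWarnings(cor(um[[an[1]]], oc[[an[2]]],
                                method = "spearman",
                                use = "pairwise.complete.obs"))
      total <- total + 1L
      if (sign(r) == as.numeric(an[3])) correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 8 / 9)
})
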