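test_that("individual summaries average only quality-passing widths", {
  an <- toy_annotations()
  s <- summarize_individuals(an)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_flukeprint_width, mean(c(2, 3)))
  expect_equal(s$n_measurements, 2)
  expect_equal(s$mean_body_length, 12) # rostrum to fluke notch, constant
  expect_equal(s$mean_fluke_span, 3.6)

  # a width measured 6 s after emergence is excluded from the mean
  an2 <- an
  an2$emergence_offset_s[an2$print_id %in% 2 &
                           grepl("width", an2$record_type)] <- 6
  expect_equal(summarize_individuals(an2)$mean_flukeprint_width, 2)
  expect_equal(summarize_individuals(an2)$n_measurements, 1)

  # degraded prints drop out of the width mean but stay in the
  # annotation table for movement analysis
  an3 <- an
  an3$degraded[an3$print_id %in% 2] <- TRUE
  expect_equal(summarize_individuals(an3)$mean_flukeprint_width, 2)
  sp <- event_speeds(an3)$tir
  expect_equal(sp$n_increments, 1) # both centroids still used
})

test_that("whales with no valid widths are excluded with a warning", {
  an <- toy_annotations()
  an$degraded[grepl("width", an$record_type)] <- TRUE
  expect_warning(s <- summarize_individuals(an), "no valid width")
  expect_equal(nrow(s), 0)
})

test_that("scaling fits recover constructed regression structure", {
  s <- data.frame(whale_id = sprintf("W%02d", 1:20),
                  age_class = rep(c("adult", "calf"), each = 10),
                  mean_flukeprint_width = seq(0.5, 5, length.out = 20))
  s$mean_body_length <- 3 * s$mean_flukeprint_width
  s$mean_fluke_span <- 0.9 * s$mean_flukeprint_width
  f <- suppressWarnings(fit_scaling(s, "body_length", "pooled"))
  expect_equal(unname(f$coefficients["width", "Estimate"]), 3, tolerance = 1e-9)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)

  # equal slopes, different intercepts: interaction non-significant,
  # class main effect strong
  set.seed(4)
  s2 <- data.frame(whale_id = sprintf("W%02d", 1:40),
                   age_class = rep(c("adult", "calf"), each = 20),
                   mean_flukeprint_width = runif(40, 1, 4))
  s2$mean_body_length <- 2 * s2$mean_flukeprint_width +
    ifelse(s2$age_class == "adult", 6, 0) + rnorm(40, 0, 0.05)
  fi <- fit_scaling(s2, "body_length", "interaction")
  expect_gt(fi$interaction_p, 0.05)
  expect_lt(fi$coefficients["age_classcalf", "Pr(>|t|)"], 1e-6)

  # constant response within a class: slope and R2 near zero
  s3 <- s2[s2$age_class == "calf", ]
  s3$mean_body_length <- 4.5 + rnorm(20, 0, 0.02)
  fc <- fit_scaling(s3, "body_length", "calf")
  expect_lt(abs(fc$coefficients["width", "Estimate"]), 0.05)
  expect_lt(fc$r2, 0.2)

  expect_error(fit_scaling(s2[s2$age_class == "adult", ], "body_length",
                           "interaction"), "both age classes")
})

test_that("interaction model never has larger residual sum of squares than pooled", {
  set.seed(9)
  for (rep in 1:5) {
    s <- data.frame(whale_id = sprintf("W%02d", 1:30),
                    age_class = sample(c("adult", "calf"), 30, TRUE,
                                       prob = c(0.7, 0.3)),
                    mean_flukeprint_width = runif(30, 1, 4))
    s$mean_body_length <- 2 + runif(30, 0, 8)
    if (length(unique(s$age_class)) < 2 || min(table(s$age_class)) < 3) next
    rss <- function(f) sum(residuals(f$model)^2)
    expect_lte(rss(fit_scaling(s, "body_length", "interaction")),
               rss(fit_scaling(s, "body_length", "pooled")) + 1e-10)
  }
})

test_that("cross-validation pools held-out predictions deterministically", {
  s <- data.frame(whale_id = sprintf("W%02d", 1:30),
                  age_class = "adult",
                  mean_flukeprint_width = seq(1, 4, length.out = 30))
  s$mean_body_length <- 1 + 2.5 * s$mean_flukeprint_width
  cv <- crossvalidate_scaling(s, "body_length", "pooled", k = 10, seed = 1)
  expect_equal(cv$cv_rmse, 0, tolerance = 1e-9)
  expect_equal(cv$cv_r2, 1, tolerance = 1e-9)
  cv2 <- crossvalidate_scaling(s, "body_length", "pooled", k = 10, seed = 1)
  expect_identical(cv, cv2)
  # pure-noise response has no held-out skill on average
  set.seed(2)
  r2 <- replicate(20, {
    s$mean_body_length <- rnorm(30)
    crossvalidate_scaling(s, "body_length", "pooled", k = 10,
                          seed = sample.int(1e6, 1))$cv_r2
  })
  expect_lt(mean(r2), 0)
  # k falls back to n with a warning when folds exceed observations
  expect_warning(cv3 <- crossvalidate_scaling(s[1:6, ], "body_length",
                                              "pooled", k = 10, seed = 1),
                 "reducing k")
  expect_equal(cv3$k, 6)
})

test_that("age classifier separates disjoint width clusters perfectly", {
  s <- data.frame(whale_id = sprintf("W%02d", 1:10),
                  age_class = rep(c("calf", "adult"), each = 5),
                  mean_flukeprint_width = c(seq(1, 2, length.out = 5),
                                            seq(3, 4.5, length.out = 5)))
  cls <- classify_age(s)
  expect_true(cls$separation_flag)
  expect_equal(cls$sensitivity, 1)
  expect_equal(cls$specificity, 1)
  expect_equal(cls$accuracy, 1)
  expect_equal(cls$auc, 1)
  expect_true(cls$youden_threshold > 2 && cls$youden_threshold < 3)
})

test_that("Youden threshold lands at the gap midpoint, smallest among ties", {
  s <- data.frame(whale_id = sprintf("W%d", 1:4),
                  age_class = c("calf", "calf", "adult", "adult"),
                  mean_flukeprint_width = c(1, 2, 3, 4))
  cls <- classify_age(s)
  expect_equal(cls$youden_threshold, 2.5)
  expect_equal(cls$youden_J, 1)
})

test_that("overlapping identical classes give no discrimination signal", {
  set.seed(6)
  w <- rnorm(60, 2.5, 0.5)
  s <- data.frame(whale_id = sprintf("W%02d", 1:60),
                  age_class = rep(c("calf", "adult"), 30),
                  mean_flukeprint_width = w)
  cls <- classify_age(s)
  expect_lt(cls$youden_J, 0.45)
  expect_lt(abs(cls$auc - 0.5), 0.2)
  expect_error(classify_age(s[s$age_class == "adult", ]), "both age classes")
})

test_that("ROC is monotone and AUC equals the brute-force Mann-Whitney statistic", {
  set.seed(13)
  for (rep in 1:3) {
    s <- data.frame(whale_id = sprintf("W%02d", 1:25),
                    age_class = rep(c("calf", "adult"), c(8, 17)),
                    mean_flukeprint_width = c(runif(8, 1, 2.6),
                                              runif(17, 2.2, 4.5)))
    cls <- classify_age(s)
    roc <- cls$roc[order(cls$roc$threshold), ]
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$specificity) >= -1e-12))
    wa <- s$mean_flukeprint_width[s$age_class == "adult"]
    wc <- s$mean_flukeprint_width[s$age_class == "calf"]
    u <- mean(outer(wa, wc, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(cls$auc, u, tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- data.frame(whale_id = sprintf("W%02d", 1:40),
                  age_class = rep(c("calf", "adult"), c(15, 25)),
                  mean_flukeprint_width = c(runif(15, 1, 2.8),
                                            runif(25, 2.0, 4.5)))
  cls <- classify_age(s)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    s$age_class == "adult", s$mean_flukeprint_width, quiet = TRUE)))
  expect_equal(cls$auc, as.numeric(ref), tolerance = 1e-9)
})
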