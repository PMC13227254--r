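make_profiles <- function(z_by_subject, group = NULL) {
  n_ring <- length(z_by_subject[[1]])
  do.call(rbind, lapply(seq_along(z_by_subject), function(i) {
    d <- data.frame(subject = sprintf("s%02d", i), ring = seq_len(n_ring),
                    value = z_by_subject[[i]], stringsAsFactors = FALSE)
    if (!is.null(group)) d$group <- group[i]
    d
  }))
}

test_that("age strata follow the closed/open boundaries", {
  co <- data.frame(subject = paste0("s", 1:6),
                   group = c(rep("hc", 5), "ms"),
                   age = c(45, 45.01, 60, 60.5, 20, 70))
  st <- assign_age_strata(co)
  expect_identical(st$stratum,
                   c("younger_hc", "middle_hc", "middle_hc", "older_hc",
                     "younger_hc", "ms"))
  co$age[2] <- NA
  err <- expect_error(assign_age_strata(co),
                      class = "pvgrad_validation_error")
  expect_match(conditionMessage(err), "s2")
})

test_that("reference_stats computes per-ring mean and n-1 SD", {
  prof <- make_profiles(list(c(0.6, 1), c(0.7, 1.2)))
  ref <- reference_stats(prof)
  expect_equal(ref$ref_mean[1], 0.65)
  expect_equal(ref$ref_sd[1], sd(c(0.6, 0.7)))
  expect_equal(ref$ref_sd[1], 0.0707, tolerance = 1e-3)

  # independent recomputation on a random table
  set.seed(10)
  prof2 <- make_profiles(replicate(8, rnorm(5), simplify = FALSE))
  ref2 <- reference_stats(prof2)
  for (k in 1:5) {
    vals <- prof2$value[prof2$ring == k]
    expect_equal(ref2$ref_mean[ref2$ring == k], mean(vals))
    expect_equal(ref2$ref_sd[ref2$ring == k],
                 sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)))
  }

  expect_error(reference_stats(make_profiles(list(c(1, 1), c(1, 2)))),
               class = "pvgrad_degenerate_reference_error")
  expect_error(reference_stats(make_profiles(list(c(1, 2)))),
               class = "pvgrad_validation_error")
})

test_that("normalization identities hold, including self-normalization", {
  set.seed(11)
  prof <- make_profiles(replicate(10, rnorm(6, 0.6, 0.1), simplify = FALSE))
  ref <- reference_stats(prof)

  at_mean <- data.frame(subject = "x", ring = 1:6, value = ref$ref_mean)
  expect_equal(normalize_profiles(at_mean, ref)$value, rep(0, 6))
  plus_sd <- data.frame(subject = "x", ring = 1:6,
                        value = ref$ref_mean + ref$ref_sd)
  expect_equal(normalize_profiles(plus_sd, ref)$value, rep(1, 6))

  z <- normalize_profiles(prof, ref)
  for (k in 1:6) {
    expect_lt(abs(mean(z$value[z$ring == k])), 1e-12)
    expect_lt(abs(sd(z$value[z$ring == k]) - 1), 1e-12)
  }

  # affine equivariance: shifting raw means by c shifts z by c / sigma_ref
  shifted <- prof; shifted$value <- prof$value + 0.3
  z2 <- normalize_profiles(shifted, ref)
  expect_equal(z2$value - z$value, 0.3 / ref$ref_sd[match(prof$ring, ref$ring)])

  expect_error(normalize_profiles(data.frame(subject = "x", ring = 7,
                                             value = 1), ref),
               class = "pvgrad_validation_error")
})

test_that("subject gradient equals the closed-form OLS slope", {
  p <- data.frame(subject = "a", ring = 1:8, value = as.numeric(0:7))
  expect_equal(fit_subject_gradient(p)$slope, 1)
  p$value <- 0.5
  expect_equal(fit_subject_gradient(p)$slope, 0)

  set.seed(12)
  p$value <- rnorm(8)
  g <- fit_subject_gradient(p)
  k <- p$ring; z <- p$value
  expect_equal(g$slope, sum((k - mean(k)) * (z - mean(z))) /
                 sum((k - mean(k))^2))
  expect_true(g$ci[1] <= g$slope && g$slope <= g$ci[2])

  expect_error(fit_subject_gradient(p[1:2, ]),
               class = "pvgrad_insufficient_data_error")
})

test_that("group gradient matches noiseless truth and subject-mean identity", {
  z <- lapply(1:6, function(i) 0.02 * (0:9) + i * 0.1)
  prof <- make_profiles(z)
  g <- fit_group_gradient(prof)
  expect_equal(g$slope, 0.02, tolerance = 1e-8)
  expect_lt(g$se, 1e-6)

  # balanced complete design: group slope = mean of subject OLS slopes
  set.seed(13)
  prof2 <- make_profiles(replicate(12, 0.02 * (1:10) + rnorm(10, 0, 0.3),
                                   simplify = FALSE))
  g2 <- fit_group_gradient(prof2)
  expect_equal(g2$slope, mean(subject_gradients(prof2)$gradient),
               tolerance = 1e-6)

  # ring mid-distance predictor rescales the slope by 1/thickness
  prof3 <- prof2; prof3$ring <- prof2$ring * 3
  g3 <- fit_group_gradient(prof3)
  expect_equal(g3$slope, g2$slope / 3, tolerance = 1e-8)

  expect_error(fit_group_gradient(prof2[prof2$subject == "s01", ]),
               class = "pvgrad_model_error")
  expect_error(fit_group_gradient(prof2[prof2$ring <= 2, ]),
               class = "pvgrad_model_error")
})

test_that("pairwise contrasts equal per-group slope differences when balanced", {
  set.seed(14)
  zs <- c(replicate(10, 0.01 * (1:10) + rnorm(10, 0, 0.2), simplify = FALSE),
          replicate(10, 0.03 * (1:10) + rnorm(10, 0, 0.2), simplify = FALSE))
  prof <- make_profiles(zs, group = rep(c("hc", "ms"), each = 10))
  ct <- compare_gradients(prof)
  expect_equal(nrow(ct), 1)
  g_hc <- fit_group_gradient(prof[prof$group == "hc", ])$slope
  g_ms <- fit_group_gradient(prof[prof$group == "ms", ])$slope
  expect_equal(abs(ct$estimate), abs(g_hc - g_ms), tolerance = 1e-8)
  expect_identical(names(ct), c("group1", "group2", "estimate", "se", "z",
                                "p", "q"))

  empty <- compare_gradients(prof[prof$group == "hc", ])
  expect_equal(nrow(empty), 0)
})
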