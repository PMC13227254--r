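# Reference normalization of ring profiles and gradient (slope) estimation.
#
# Profiles are long data.frames with columns subject, ring, value (plus
# optional group and covariates). The "gradient" is the slope of the
# normalized metric across ring index: positive means values rise away from
# the ventricles on the z scale.

.hc_default <- c("hc", "younger_hc", "middle_hc", "older_hc")

#' Assign HC age strata
#'
#' Healthy controls are split into younger (age <= 45), middle-aged
#' (45 < age <= 60) and older (age > 60) strata; subjects in disease groups
#' keep their group label.
#'
#' @param cohort data.frame with `subject`, `group`, `age`.
#' @param hc_groups group labels treated as healthy controls.
#' @return the cohort with a `stratum` column.
#' @export
assign_age_strata <- function(cohort, hc_groups = .hc_default) {
  is_hc <- cohort$group %in% hc_groups
  bad <- is_hc & is.na(cohort$age)
  if (any(bad)) {
    stop_pv("missing age for HC subjects: ",
            paste(cohort$subject[bad], collapse = ", "),
            class = "pvgrad_validation_error")
  }
  stratum <- cohort$group
  stratum[is_hc] <- ifelse(cohort$age[is_hc] <= 45, "younger_hc",
                           ifelse(cohort$age[is_hc] <= 60, "middle_hc",
                                  "older_hc"))
  cohort$stratum <- stratum
  cohort
}

#' Per-ring reference statistics from the reference stratum
#'
#' Sample mean and SD (denominator n - 1) of the raw ring means over the
#' reference subjects (by default the younger-HC stratum), per ring. These
#' are the operands of the z-score normalization.
#'
#' @param profiles long data.frame (`subject`, `ring`, `value`) restricted to
#'   the reference subjects.
#' @return data.frame `ring, ref_mean, ref_sd, n_ref` of class
#'   `reference_stats`.
#' @export
reference_stats <- function(profiles) {
  sp <- split(profiles$value[!is.na(profiles$value)],
              profiles$ring[!is.na(profiles$value)])
  n <- vapply(sp, length, 1L)
  if (any(n < 2)) {
    stop_pv("rings with < 2 reference values: ",
            paste(names(sp)[n < 2], collapse = ", "),
            class = "pvgrad_validation_error")
  }
  out <- data.frame(ring = as.integer(names(sp)),
                    ref_mean = vapply(sp, mean, 1),
                    ref_sd = vapply(sp, sd, 1),
                    n_ref = n, row.names = NULL)
  if (any(out$ref_sd == 0)) {
    stop_pv("degenerate reference: zero SD in ring ",
            paste(out$ring[out$ref_sd == 0], collapse = ", "),
            class = "pvgrad_degenerate_reference_error")
  }
  class(out) <- c("reference_stats", class(out))
  out[order(out$ring), ]
}

#' z-score normalize ring profiles against reference statistics
#'
#' `z_k = (m_k - ref_mean_k) / ref_sd_k` per ring. Missing ring means stay
#' missing.
#'
#' @param profiles long data.frame (`subject`, `ring`, `value`, ...).
#' @param ref a [reference_stats()] covering every ring present.
#' @return the same data.frame with `value` replaced by the z-score.
#' @export
normalize_profiles <- function(profiles, ref) {
  stopifnot(inherits(ref, "reference_stats"))
  idx <- match(profiles$ring, ref$ring)
  if (anyNA(idx[!is.na(profiles$value)])) {
    miss <- unique(profiles$ring[is.na(idx) & !is.na(profiles$value)])
    stop_pv("rings absent from reference stats: ",
            paste(miss, collapse = ", "),
            class = "pvgrad_validation_error")
  }
  profiles$value <- (profiles$value - ref$ref_mean[idx]) / ref$ref_sd[idx]
  profiles
}

.new_gradient_estimate <- function(scope, slope, se, df = Inf, n_subjects,
                                   n_rings) {
  crit <- if (is.finite(df)) qt(0.975, df) else qnorm(0.975)
  stat <- slope / se
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  structure(list(scope = scope, slope = slope, se = se,
                 ci = c(lower = slope - crit * se, upper = slope + crit * se),
                 p = p, n_subjects = n_subjects, n_rings = n_rings),
            class = "gradient_estimate")
}

#' @export
print.gradient_estimate <- function(x, ...) {
  cat(sprintf("%s gradient: %.4g (SE %.3g, 95%% CI [%.4g, %.4g], p = %.3g)\n",
              x$scope, x$slope, x$se, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Group-level periventricular gradient via a linear mixed model
#'
#' Fits `value ~ ring + (1 | subject)` (optionally with a random slope) by
#' REML and reports the fixed ring slope with its Wald SE, 95% CI and p.
#' The slope is in z-units per ring; divide by the ring thickness for
#' z-units per mm.
#'
#' @param profiles long data.frame (`subject`, `ring`, `value`) for one group.
#' @param random_slope add a per-subject random slope (default `FALSE`).
#' @return a `gradient_estimate`.
#' @export
fit_group_gradient <- function(profiles, random_slope = FALSE) {
  d <- profiles[!is.na(profiles$value), , drop = FALSE]
  n_sub <- length(unique(d$subject))
  n_ring <- length(unique(d$ring))
  if (n_sub < 2) stop_pv("need >= 2 subjects", class = "pvgrad_model_error")
  if (n_ring < 3) stop_pv("need >= 3 distinct rings",
                          class = "pvgrad_model_error")
  form <- if (random_slope) value ~ ring + (ring | subject)
          else value ~ ring + (1 | subject)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  co <- summary(fit)$coefficients
  .new_gradient_estimate("group", co["ring", "Estimate"],
                         co["ring", "Std. Error"], Inf, n_sub, n_ring)
}

#' Subject-level gradient by ordinary least squares
#'
#' OLS slope of the (normalized) ring value on ring index for one subject.
#'
#' @param profile long data.frame for a single subject.
#' @return a `gradient_estimate`.
#' @export
fit_subject_gradient <- function(profile) {
  d <- profile[!is.na(profile$value), , drop = FALSE]
  if (nrow(d) < 3) {
    stop_pv("subject gradient needs >= 3 non-missing rings",
            class = "pvgrad_insufficient_data_error")
  }
  fit <- lm(value ~ ring, data = d)
  # perfect fits (noise-free phantoms) trigger a harmless summary warning
  co <- suppressWarnings(summary(fit))$coefficients
  .new_gradient_estimate("subject", co["ring", "Estimate"],
                         co["ring", "Std. Error"], fit$df.residual,
                         1L, nrow(d))
}

#' Per-subject gradients for a whole profile table
#'
#' @param profiles long data.frame with `subject`, `ring`, `value` (and
#'   optionally `group`, carried through).
#' @return data.frame `subject[, group], gradient, se, n_rings`.
#' @export
subject_gradients <- function(profiles) {
  sp <- split(profiles, profiles$subject)
  rows <- lapply(sp, function(d) {
    g <- fit_subject_gradient(d)
    out <- data.frame(subject = d$subject[1], gradient = g$slope, se = g$se,
                      n_rings = g$n_rings, stringsAsFactors = FALSE)
    if ("group" %in% names(d)) out$group <- d$group[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject), ]
}

#' Pairwise slope contrasts between groups
#'
#' Fits a pooled mixed model `value ~ group * ring + (1 | subject)` and tests
#' every pairwise difference of group slopes as a general linear hypothesis
#' on the group-by-ring interaction. Raw p-values are Benjamini-Hochberg
#' adjusted across the contrast family.
#'
#' @param profiles long data.frame with `subject`, `group`, `ring`, `value`.
#' @return data.frame `group1, group2, estimate, se, z, p, q` (empty with a
#'   single group).
#' @export
compare_gradients <- function(profiles) {
  d <- profiles[!is.na(profiles$value), , drop = FALSE]
  d$group <- factor(d$group)
  groups <- levels(d$group)
  if (length(groups) < 2) {
    return(data.frame(group1 = character(), group2 = character(),
                      estimate = numeric(), se = numeric(), z = numeric(),
                      p = numeric(), q = numeric()))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ group * ring + (1 | subject), data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  fe <- lme4::fixef(fit)
  pairs <- utils::combn(groups, 2)
  K <- matrix(0, ncol(pairs), length(fe),
              dimnames = list(NULL, names(fe)))
  slope_term <- function(g) {
    if (g == groups[1]) character(0) else paste0("group", g, ":ring")
  }
  for (j in seq_len(ncol(pairs))) {
    t1 <- slope_term(pairs[1, j]); t2 <- slope_term(pairs[2, j])
    if (length(t1)) K[j, t1] <- 1
    if (length(t2)) K[j, t2] <- K[j, t2] - 1
  }
  gh <- multcomp::glht(fit, linfct = K)
  sm <- summary(gh, test = multcomp::adjusted("none"))
  est <- as.numeric(sm$test$coefficients)
  se <- as.numeric(sm$test$sigma)
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], estimate = est,
             se = se, z = z, p = p, q = p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}
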