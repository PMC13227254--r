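# Confounder-adjusted regression and bootstrap mediation analysis.
#
# Mediation uses the product-of-coefficients estimator for linear models:
# a (mediator ~ exposure + confounders), b (outcome ~ mediator + exposure +
# confounders), indirect = a * b, direct = exposure coefficient of the
# outcome model, total = direct + indirect, with percentile bootstrap CIs
# over case resampling. The mediation effect size is the percentage mediated
# PM = 100 * indirect / total.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), monotone in rank. Thin validated
#' wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_pv("p-values must lie in [0, 1]", class = "pvgrad_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Linear regression of an outcome on a predictor with confounders
#'
#' Least-squares coefficient of `predictor` with the stated confounders
#' partialled out; CI and p from the t distribution. WMH volumes can be
#' log-transformed in place via `log_transform` (natural log plus offset).
#'
#' @param data data.frame of complete observations (incomplete rows dropped).
#' @param outcome,predictor,confounders column names.
#' @param log_transform columns to replace by `log(x + log_offset)` first.
#' @param log_offset offset added before the log (default 0).
#' @return data.frame of class `regression_result`: coefficient, SE, 95% CI,
#'   p, n.
#' @export
adjusted_regression <- function(data, outcome, predictor,
                                confounders = character(0),
                                log_transform = character(0),
                                log_offset = 0) {
  vars <- c(outcome, predictor, confounders)
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  for (v in intersect(log_transform, vars)) d[[v]] <- log(d[[v]] + log_offset)
  if (nrow(d) < length(vars) + 2) {
    stop_pv("too few complete cases", class = "pvgrad_validation_error")
  }
  X <- model.matrix(as.formula(paste("~", paste(c(predictor, confounders),
                                                collapse = "+"))), d)
  if (qr(X)$rank < ncol(X)) {
    stop_pv("rank-deficient (collinear) design",
            class = "pvgrad_rank_deficiency_error")
  }
  fit <- lm.fit(X, d[[outcome]])
  dfres <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / dfres
  vc <- sigma2 * chol2inv(chol(crossprod(X)))
  est <- fit$coefficients[predictor]
  se <- sqrt(vc[match(predictor, colnames(X)), match(predictor, colnames(X))])
  crit <- qt(0.975, dfres)
  out <- data.frame(outcome = outcome, predictor = predictor,
                    confounders = paste(confounders, collapse = "+"),
                    coefficient = unname(est), se = se,
                    ci_lower = unname(est - crit * se),
                    ci_upper = unname(est + crit * se),
                    p = 2 * pt(-abs(est / se), dfres), n = nrow(d),
                    stringsAsFactors = FALSE)
  class(out) <- c("regression_result", class(out))
  out
}

# single pass of the product-of-coefficients estimator on prepared matrices;
# returns c(indirect_1..J, direct, total)
.med_point <- function(Xm, Xy, M, y, n_med) {
  a <- vapply(seq_len(n_med), function(j)
    .lm.fit(Xm, M[, j])$coefficients[2], 1)
  fy <- .lm.fit(Xy, y)
  b <- fy$coefficients[2 + seq_len(n_med)]
  direct <- fy$coefficients[2]
  ind <- a * b
  c(ind, direct, direct + sum(ind))
}

.mediate_engine <- function(data, exposure, mediators, outcome, confounders,
                            log_transform, log_offset, n_boot, seed,
                            clip_pm = FALSE) {
  if (anyDuplicated(mediators)) {
    stop_pv("duplicated mediators", class = "pvgrad_rank_deficiency_error")
  }
  if (n_boot < 1000) stop_pv("n_boot must be >= 1000",
                             class = "pvgrad_validation_error")
  vars <- c(exposure, mediators, outcome, confounders)
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  for (v in intersect(log_transform, vars)) d[[v]] <- log(d[[v]] + log_offset)
  zero_var <- vapply(vars, function(v) length(unique(d[[v]])) < 2, TRUE)
  if (any(zero_var)) {
    stop_pv("zero variance in: ", paste(vars[zero_var], collapse = ", "),
            class = "pvgrad_validation_error")
  }
  n <- nrow(d)
  J <- length(mediators)
  # confounders may be factors/characters (e.g. group); expand to dummies
  Cmat <- if (length(confounders)) {
    cm <- model.matrix(as.formula(paste("~", paste(confounders,
                                                   collapse = "+"))), d)
    cm[, -1, drop = FALSE]
  } else NULL
  Xm <- cbind(1, d[[exposure]], Cmat)
  Xy <- cbind(1, d[[exposure]], as.matrix(d[, mediators, drop = FALSE]), Cmat)
  if (qr(Xy)$rank < ncol(Xy)) {
    stop_pv("rank-deficient outcome model (collinear mediators?)",
            class = "pvgrad_rank_deficiency_error")
  }
  M <- as.matrix(d[, mediators, drop = FALSE])
  y <- d[[outcome]]
  pt_est <- .med_point(Xm, Xy, M, y, J)
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(bb) {
      idx <- sample.int(n, n, replace = TRUE)
      .med_point(Xm[idx, , drop = FALSE], Xy[idx, , drop = FALSE],
                 M[idx, , drop = FALSE], y[idx], J)
    }, numeric(J + 2)))
  })
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  se <- apply(boot, 2, sd)
  # two-sided bootstrap-normal p per effect
  p <- 2 * pnorm(-abs(pt_est / se))
  eff <- c(paste0("indirect_", mediators), "direct", "total")
  total <- pt_est[J + 2]
  pm <- if (abs(total) < 1e-12) rep(NA_real_, J)
        else 100 * pt_est[seq_len(J)] / total
  pm_reason <- if (abs(total) < 1e-12) "total effect ~ 0" else NA_character_
  if (clip_pm && !all(is.na(pm))) pm <- pmin(pmax(pm, 0), 100)
  structure(list(
    exposure = exposure, mediators = mediators, outcome = outcome,
    confounders = confounders,
    effects = data.frame(effect = eff, estimate = pt_est,
                         ci_lower = ci[1, ], ci_upper = ci[2, ],
                         boot_se = se, p = p, stringsAsFactors = FALSE),
    pm = setNames(pm, mediators), pm_undefined_reason = pm_reason,
    n = n, n_boot = n_boot, seed = seed), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: %s -> {%s} -> %s (n = %d, %d bootstrap draws)\n",
              x$exposure, paste(x$mediators, collapse = ", "), x$outcome,
              x$n, x$n_boot))
  print(x$effects, row.names = FALSE, digits = 4)
  for (m in x$mediators) {
    cat(sprintf("  PM[%s] = %s\n", m,
                if (is.na(x$pm[[m]])) paste0("undefined (",
                                             x$pm_undefined_reason, ")")
                else sprintf("%.2f%%", x$pm[[m]])))
  }
  invisible(x)
}

#' Single-mediator bootstrap mediation analysis
#'
#' Product-of-coefficients estimate of the indirect effect of `exposure` on
#' `outcome` through `mediator`, with percentile bootstrap 95% CIs (case
#' resampling) and the percentage mediated PM = 100 * indirect / total. PM is
#' reported unclipped by default (it can be negative or exceed 100 when
#' direct and indirect effects oppose); `clip_pm = TRUE` truncates it to
#' `[0, 100]`.
#'
#' @param data data.frame; incomplete cases are dropped.
#' @param exposure,mediator,outcome,confounders column names.
#' @param n_boot bootstrap draws (>= 1000).
#' @param seed mandatory integer seed for the bootstrap.
#' @param log_transform,log_offset see [adjusted_regression()].
#' @param clip_pm truncate PM to `[0, 100]`.
#' @return a `mediation_result`.
#' @export
mediate_single <- function(data, exposure, mediator, outcome,
                           confounders = character(0), n_boot = 5000, seed,
                           log_transform = character(0), log_offset = 0,
                           clip_pm = FALSE) {
  stopifnot(length(mediator) == 1)
  .mediate_engine(data, exposure, mediator, outcome, confounders,
                  log_transform, log_offset, n_boot, seed, clip_pm)
}

#' Parallel-mediator bootstrap mediation analysis
#'
#' As [mediate_single()] but with several mediators entered jointly in the
#' outcome model; per-mediator indirect effects are `a_j * b_j` and the
#' bootstrap resamples cases jointly.
#'
#' @inheritParams mediate_single
#' @param mediators character vector of distinct mediator columns.
#' @return a `mediation_result`.
#' @export
mediate_parallel <- function(data, exposure, mediators, outcome,
                             confounders = character(0), n_boot = 5000, seed,
                             log_transform = character(0), log_offset = 0,
                             clip_pm = FALSE) {
  .mediate_engine(data, exposure, mediators, outcome, confounders,
                  log_transform, log_offset, n_boot, seed, clip_pm)
}
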