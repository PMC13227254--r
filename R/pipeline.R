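# End-to-end synthetic experiment: simulate -> rings/profiles -> gradients
# -> mediation -> PLS -> report, with per-stage caching in the output
# directory so a rerun with an identical config and seed reproduces every
# table byte for byte.

#' Default pipeline configuration
#'
#' All analysis thresholds are configurable here and default to the standard
#' design: 3 mm x 10 rings starting at 3 mm, younger-HC reference
#' normalization, |Z| > 5 with q < 0.001 for gene lists, FDR 0.05 elsewhere.
#'
#' @param seed root seed (mandatory for every downstream resampling step).
#' @param out_dir output directory for stage tables and the report.
#' @return nested configuration list of class `pv_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("pvgrad_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    rings = list(thickness_mm = 3, n_rings = 10, start_mm = 3),
    cohort = list(groups = NULL, scm = NULL),
    normalize = "reference",
    reference_stratum = "younger_hc",
    mediation = list(exposure = "cpv",
                     outcomes = c("wmh_volume", "nawm_ndi", "wmv", "gmv"),
                     confounders = c("age", "sex", "tiv", "group"),
                     n_boot = 1000, log_transform = "wmh_volume",
                     log_offset = 0),
    scores = list(outcome = "mmse",
                  mediators = c("wmv", "gmv")),
    expression = list(n_genes = 1000, n_associated = 50, effect_size = 1,
                      noise_sd = 0.1, samples_per_ring = 3),
    pls = list(group = "older_hc", n_perm = 1000, n_boot = 500,
               z_threshold = 5, q_threshold = 0.001)
  ), class = "pv_config")
}

#' Noise-free pipeline configuration
#'
#' Every measurement-level disturbance (ring noise, intercept spread, outcome
#' and score noise) is set to zero and normalization is bypassed, so the
#' linear structural causal model propagates exactly: recovered group slopes
#' equal the realized generating slopes, subject gradients equal the true
#' `b_i`, and the outcome-model paths (`b`, `c_direct`) are recovered to
#' numerical tolerance. The mediator's own exogenous disturbance
#' (`slope_sd`) is kept small but positive: with it at zero the mediator
#' would be an exact linear function of exposure and group and the mediation
#' model would be unidentifiable (rank-deficient).
#'
#' @inheritParams default_config
#' @return a `pv_config`.
#' @export
noise_free_config <- function(seed = 1, out_dir = tempfile("pvgrad_run_")) {
  cfg <- default_config(seed, out_dir)
  groups <- .default_groups()
  for (nm in names(groups)) {
    groups[[nm]]$slope_sd <- 0.005
    groups[[nm]]$intercept_sd <- 0
    groups[[nm]]$voxel_noise_sd <- 0
  }
  cfg$cohort$groups <- groups
  cfg$cohort$scm <- list(a = 0.008, b = 30, c_direct = 0.3, cpv_mean = 2,
                         cpv_sd = 0.5, outcome_noise_sd = 0,
                         score_coefs = c(wmv = 0.05, gmv = 0.05),
                         score_noise_sd = 0)
  cfg$normalize <- "none"
  # with zero outcome noise the four outcomes are numerically identical, so
  # a parallel-mediator model would be exactly collinear; keep one mediator
  cfg$scores$mediators <- "gmv"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override [default_config()] entries; the seed
#' is mandatory.
#'
#' @param file path to a YAML (or JSON) configuration file.
#' @return a `pv_config`.
#' @export
read_config <- function(file) {
  raw <- if (grepl("\\.json$", file)) jsonlite::read_json(file,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(file)
  if (is.null(raw$seed)) {
    stop_pv("config must declare a seed", class = "pvgrad_validation_error")
  }
  cfg <- default_config(seed = raw$seed,
                        out_dir = raw$out_dir %||% tempfile("pvgrad_run_"))
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_in(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), raw[setdiff(names(raw), c("seed", "out_dir"))]),
            class = "pv_config")
}

#' Validate an input bundle
#'
#' Checks NIfTI grid and spacing agreement across masks and metric volumes,
#' mask binarity, cohort column presence and types, and expression table
#' shape. Returns a diagnostics table distinguishing fatal errors from
#' warnings rather than stopping, so all problems surface at once.
#'
#' @param paths named list; any of `seg_dir` (directory of mask volumes),
#'   `metrics` (metric NIfTI paths), `cohort` (TSV path), `expression`
#'   (TSV path).
#' @return data.frame `check, level, message` with `level` in
#'   `ok | warning | fatal`.
#' @export
validate_inputs <- function(paths) {
  diag <- list()
  note <- function(check, level, message) {
    diag[[length(diag) + 1L]] <<- data.frame(check = check, level = level,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  ref_dim <- NULL; ref_pix <- NULL
  if (!is.null(paths$seg_dir)) {
    for (nm in c("ventricle", "wm", "wmh", "gm", "brain")) {
      f <- file.path(paths$seg_dir, paste0(nm, ".nii.gz"))
      if (!file.exists(f)) {
        if (nm %in% c("wmh", "gm")) next
        note(paste0("mask:", nm), "fatal", paste0("missing volume ", f))
        next
      }
      img <- RNifti::readNifti(f)
      if (is.null(ref_dim)) { ref_dim <- dim(img); ref_pix <- RNifti::pixdim(img) }
      if (!identical(dim(img), ref_dim)) {
        note(paste0("mask:", nm), "fatal", "grid mismatch across masks")
      } else if (any(abs(RNifti::pixdim(img)[1:3] - ref_pix[1:3]) > 1e-6)) {
        note(paste0("mask:", nm), "fatal", "voxel spacing mismatch")
      } else {
        u <- unique(as.vector(img))
        if (!all(u %in% c(0, 1))) {
          note(paste0("mask:", nm), "fatal",
               paste0("mask not binary (values ",
                      paste(head(sort(u), 4), collapse = ","), ")"))
        } else note(paste0("mask:", nm), "ok", "binary, grid consistent")
      }
    }
  }
  if (!is.null(paths$metrics)) {
    for (f in paths$metrics) {
      img <- RNifti::readNifti(f)
      if (!is.null(ref_dim) && !identical(dim(img), ref_dim)) {
        note(paste0("metric:", basename(f)), "fatal",
             "metric grid differs from mask grid")
      } else note(paste0("metric:", basename(f)), "ok", "grid consistent")
    }
  }
  if (!is.null(paths$cohort)) {
    co <- read_tsv(paths$cohort)
    need <- c("subject", "group", "age")
    miss <- setdiff(need, names(co))
    if (length(miss)) {
      note("cohort", "fatal", paste0("missing columns: ",
                                     paste(miss, collapse = ", ")))
    } else if (!is.numeric(co$age)) {
      note("cohort", "fatal", "age is not numeric")
    } else note("cohort", "ok", paste0(nrow(co), " subjects"))
    if ("tiv" %in% names(co) && any(co$tiv <= 0, na.rm = TRUE)) {
      note("cohort", "warning", "non-positive TIV values")
    }
  }
  if (!is.null(paths$expression)) {
    ex <- read_tsv(paths$expression)
    if (!"distance_mm" %in% names(ex)) {
      note("expression", "fatal", "missing distance_mm column")
    } else {
      gene_cols <- setdiff(names(ex), c("sample", "ring", "distance_mm"))
      if (length(gene_cols) < 1) {
        note("expression", "fatal", "no gene columns")
      } else note("expression", "ok",
                  paste0(nrow(ex), " samples x ", length(gene_cols), " genes"))
    }
  }
  out <- do.call(rbind, diag)
  if (is.null(out)) out <- data.frame(check = character(), level = character(),
                                      message = character())
  out
}

# synthetic cell-type gene sets built from the expression ground truth:
# "endothelial" is seeded with negatively associated genes, "neuron" with
# positive ones, the remaining sets with null genes only
.synthetic_gene_sets <- function(truth, seed) {
  with_seed(seed, {
    neg <- truth$gene[truth$sign < 0]
    pos <- truth$gene[truth$sign > 0]
    nul <- truth$gene[!truth$associated]
    list(endothelial = c(neg, sample(nul, max(5, length(neg) %/% 2))),
         neuron = c(pos, sample(nul, max(5, length(pos) %/% 2))),
         astrocyte = sample(nul, 40),
         microglia = sample(nul, 40),
         oligodendrocyte = sample(nul, 40))
  })
}

.stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — simulate, gradient (reference
#' normalization, group slopes, contrasts), mediation, PLS/enrichment — and
#' writes every result table (tab-separated) plus a JSON report into
#' `config$out_dir`. Stage outputs already present are reused (resume); a
#' stage failure halts with the failing stage named. Identical config and
#' seed reproduce identical tables.
#'
#' @param config a `pv_config` (see [default_config()]).
#' @param force recompute even when cached stage outputs exist.
#' @return invisibly, a `run_report` list with the parameter echo, per-stage
#'   tables and wall-clock seconds per stage.
#' @export
run_pipeline <- function(config = default_config(), force = FALSE) {
  stopifnot(inherits(config, "pv_config"))
  if (is.null(config$seed)) stop_pv("config seed is mandatory",
                                    class = "pvgrad_validation_error")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = unclass(config),
                 versions = list(r = R.version.string,
                                 pvgrad = as.character(utils::packageVersion("pvgrad"))),
                 stages = list(), timing_s = list(), warnings = character())
  run_stage <- function(name, outputs, fn) {
    t0 <- Sys.time()
    paths <- vapply(outputs, function(o) .stage_path(config, o), "")
    if (!force && all(file.exists(paths))) {
      res <- lapply(paths, read_tsv)
      names(res) <- sub("\\.tsv$", "", outputs)
      report$stages[[name]] <<- c(res, list(cached = TRUE))
    } else {
      res <- tryCatch(fn(), error = function(e) {
        stop_pv("stage '", name, "' failed: ", conditionMessage(e),
                class = "pvgrad_stage_error")
      })
      for (o in names(res)) write_tsv(res[[o]], .stage_path(config,
                                                            paste0(o, ".tsv")))
      report$stages[[name]] <<- c(res, list(cached = FALSE))
    }
    report$timing_s[[name]] <<- as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs"))
    invisible(NULL)
  }

  # -- simulate ---------------------------------------------------------
  cs <- do.call(cohort_spec, c(
    list(seed = config$seed, n_rings = config$rings$n_rings),
    Filter(Negate(is.null), config$cohort[c("groups", "scm")])))
  sim <- make_cohort(cs)
  run_stage("simulate", c("cohort.tsv", "profiles.tsv", "truth_subjects.tsv"),
            function() list(cohort = sim$cohort, profiles = sim$profiles,
                            truth_subjects = sim$truth$subjects))

  # -- gradient ---------------------------------------------------------
  cohort <- assign_age_strata(sim$cohort)
  profiles <- merge(sim$profiles,
                    cohort[, c("subject", "stratum")], by = "subject")
  if (identical(config$normalize, "reference")) {
    ref <- reference_stats(
      profiles[profiles$stratum == config$reference_stratum, ])
    profiles <- normalize_profiles(profiles, ref)
  }
  profiles$group <- profiles$stratum
  run_stage("gradient",
            c("group_gradients.tsv", "contrasts.tsv", "subject_gradients.tsv"),
            function() {
    gg <- do.call(rbind, lapply(split(profiles, profiles$group), function(d) {
      g <- fit_group_gradient(d)
      data.frame(group = d$group[1], slope = g$slope, se = g$se,
                 ci_lower = g$ci[1], ci_upper = g$ci[2], p = g$p,
                 n_subjects = g$n_subjects, stringsAsFactors = FALSE)
    }))
    rownames(gg) <- NULL
    list(group_gradients = gg,
         contrasts = compare_gradients(profiles),
         subject_gradients = subject_gradients(profiles))
  })
  subj_grad <- read_tsv(.stage_path(config, "subject_gradients.tsv"))
  adata <- merge(cohort, subj_grad[, c("subject", "gradient")], by = "subject")

  # -- mediation --------------------------------------------------------
  med_cfg <- config$mediation
  run_stage("mediation", c("mediation.tsv", "score_mediation.tsv"),
            function() {
    rows <- lapply(seq_along(med_cfg$outcomes), function(i) {
      out <- med_cfg$outcomes[i]
      m <- mediate_single(adata, exposure = med_cfg$exposure,
                          mediator = "gradient", outcome = out,
                          confounders = med_cfg$confounders,
                          n_boot = med_cfg$n_boot,
                          seed = child_seed(config$seed, 9000 + i),
                          log_transform = med_cfg$log_transform,
                          log_offset = med_cfg$log_offset)
      eff <- m$effects
      data.frame(outcome = out,
                 indirect = eff$estimate[1],
                 indirect_lo = eff$ci_lower[1], indirect_hi = eff$ci_upper[1],
                 direct = eff$estimate[2], total = eff$estimate[3],
                 pm = unname(m$pm[1]), p = eff$p[1],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- fdr_adjust(tab$p)
    sc <- config$scores
    mp <- mediate_parallel(adata, exposure = "gradient",
                           mediators = sc$mediators, outcome = sc$outcome,
                           confounders = med_cfg$confounders,
                           n_boot = med_cfg$n_boot,
                           seed = child_seed(config$seed, 9500))
    eff <- mp$effects
    sc_tab <- data.frame(outcome = sc$outcome,
                         effect = eff$effect, estimate = eff$estimate,
                         ci_lower = eff$ci_lower, ci_upper = eff$ci_upper,
                         p = eff$p, stringsAsFactors = FALSE)
    list(mediation = tab, score_mediation = sc_tab)
  })

  # -- pls --------------------------------------------------------------
  atlas <- build_rings(array(0, c(1, 1, 1)),
                       thickness_mm = config$rings$thickness_mm,
                       n_rings = config$rings$n_rings,
                       start_mm = config$rings$start_mm)
  pls_prof <- profiles[profiles$group == config$pls$group, ]
  y <- vapply(split(pls_prof$value, pls_prof$ring), mean, 1)
  y <- y[order(as.integer(names(y)))]
  es <- do.call(expression_spec, c(config$expression,
                                   list(seed = child_seed(config$seed, 7000))))
  expr <- make_expression(es, y, atlas)
  run_stage("pls", c("pls_genes.tsv", "enrichment.tsv", "gene_lists.tsv",
                     "pls_summary.tsv"),
            function() {
    ring_x <- aggregate_expression_by_ring(expr$samples, atlas)
    used <- as.integer(rownames(ring_x$X))
    fit <- fit_pls1(ring_x, y[used])
    perm <- permute_varexp(fit, n_perm = config$pls$n_perm,
                           seed = child_seed(config$seed, 7100))
    gz <- bootstrap_gene_z(fit, n_boot = config$pls$n_boot,
                           seed = child_seed(config$seed, 7200))
    lists <- select_genes(gz, config$pls$z_threshold, config$pls$q_threshold)
    sets <- .synthetic_gene_sets(expr$truth, child_seed(config$seed, 7300))
    enr <- do.call(rbind, lapply(c("pls1_neg", "pls1_pos"), function(side) {
      if (!length(lists[[side]])) return(NULL)
      e <- celltype_enrichment(lists[[side]], sets, expr$truth$gene)
      cbind(list_id = side, e)
    }))
    if (is.null(enr)) enr <- data.frame(list_id = character(),
                                        set = character(), p = numeric())
    gl <- data.frame(
      list_id = rep(c("pls1_neg", "pls1_pos"),
                    c(length(lists$pls1_neg), length(lists$pls1_pos))),
      gene = c(lists$pls1_neg, lists$pls1_pos), stringsAsFactors = FALSE)
    list(pls_genes = gz, enrichment = enr, gene_lists = gl,
         pls_summary = data.frame(varexp = fit$varexp, perm_p = perm$p,
                                  n_perm = perm$n_perm,
                                  n_pls1_neg = length(lists$pls1_neg),
                                  n_pls1_pos = length(lists$pls1_pos)))
  })

  report$stages$simulate$truth_paths <- sim$truth$paths
  write_json_summary(list(
    parameters = report$parameters,
    versions = report$versions,
    group_gradients = read_tsv(.stage_path(config, "group_gradients.tsv")),
    contrasts = read_tsv(.stage_path(config, "contrasts.tsv")),
    mediation = read_tsv(.stage_path(config, "mediation.tsv")),
    pls_summary = read_tsv(.stage_path(config, "pls_summary.tsv"))
  ), .stage_path(config, "report.json"))
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pvgrad run:", length(x$stages), "stages in",
      x$parameters$out_dir, "\n")
  for (nm in names(x$timing_s)) {
    cat(sprintf("  %-10s %6.2f s%s\n", nm, x$timing_s[[nm]],
                if (isTRUE(x$stages[[nm]]$cached)) " (cached)" else ""))
  }
  invisible(x)
}
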