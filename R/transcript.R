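# Imaging transcriptomics: ring-wise expression vs the ring-wise gradient
# profile. PLS1 is the first partial-least-squares component: with gene
# columns standardized across rings and the response centred, the weight
# vector is X'y normalized to unit length; the component score is X w and
# the variance explained is the R^2 of the response regressed on that score.

#' Aggregate sample-level expression into a ring x gene matrix
#'
#' Samples are assigned to rings by the atlas's half-open distance bounds;
#' entries are per-ring per-gene means. Rings with no samples are excluded.
#'
#' @param samples data.frame with `distance_mm` plus one numeric column per
#'   gene (columns `sample` and `ring`, if present, are ignored as genes).
#' @param atlas a [build_rings()] atlas.
#' @return list of class `ring_expression`: `X` (rings x genes matrix,
#'   rownames = ring index), `n_samples` per ring.
#' @export
aggregate_expression_by_ring <- function(samples, atlas) {
  stopifnot(inherits(atlas, "ring_atlas"), "distance_mm" %in% names(samples))
  gene_cols <- setdiff(names(samples), c("sample", "ring", "distance_mm"))
  d <- samples$distance_mm
  ring <- findInterval(d, c(atlas$bounds_mm$lower,
                            atlas$bounds_mm$upper[atlas$n_rings]))
  ring[d >= atlas$bounds_mm$upper[atlas$n_rings]] <- 0L
  keep <- ring >= 1L
  if (sum(keep) == 0 || length(unique(ring[keep])) < 3) {
    stop_pv("fewer than 3 populated rings",
            class = "pvgrad_insufficient_data_error")
  }
  f <- factor(ring[keep], levels = sort(unique(ring[keep])))
  m <- as.matrix(samples[keep, gene_cols, drop = FALSE])
  X <- rowsum(m, f) / as.integer(table(f))
  rownames(X) <- levels(f)
  structure(list(X = X, n_samples = setNames(as.integer(table(f)),
                                             levels(f))),
            class = "ring_expression")
}

.standardize_cols <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  keep <- s > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], `/`)
  list(X = Xs, dropped = colnames(X)[!keep])
}

# core PLS1 on an already-standardized X and centred y
.pls1_core <- function(Xs, yc) {
  w <- drop(crossprod(Xs, yc))
  nw <- sqrt(sum(w^2))
  w <- w / nw
  t_score <- drop(Xs %*% w)
  vexp <- if (sd(t_score) == 0) 0 else cor(yc, t_score)^2
  list(weights = w, scores = t_score, varexp = vexp)
}

#' First PLS component linking ring expression to the gradient profile
#'
#' Gene columns are standardized (mean 0, SD 1 across rings; zero-variance
#' genes are dropped with a warning) and the response centred. The PLS1
#' weight vector is proportional to `X'y` with unit Euclidean norm; the
#' variance explained is the squared correlation between the response and
#' the first component score.
#'
#' @param X `ring_expression` or plain rings x genes matrix.
#' @param y numeric response per ring (e.g. the group gradient profile:
#'   mean normalized metric per ring).
#' @return list of class `pls1_fit`: `weights`, `scores`, `varexp`, plus the
#'   standardized matrix and centred response used.
#' @export
fit_pls1 <- function(X, y) {
  if (inherits(X, "ring_expression")) X <- X$X
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (sd(y) == 0) {
    stop_pv("constant response: PLS1 undefined",
            class = "pvgrad_degenerate_response_error")
  }
  st <- .standardize_cols(X)
  if (length(st$dropped)) {
    warning("dropping zero-variance genes: ",
            paste(head(st$dropped, 5), collapse = ", "),
            if (length(st$dropped) > 5) ", ...")
  }
  yc <- y - mean(y)
  core <- .pls1_core(st$X, yc)
  structure(list(weights = core$weights, scores = core$scores,
                 varexp = core$varexp, X_std = st$X, y_centred = yc,
                 dropped = st$dropped), class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d genes over %d rings, variance explained %.3f\n",
              ncol(x$X_std), nrow(x$X_std), x$varexp))
  invisible(x)
}

#' Permutation test of the variance explained by PLS1
#'
#' The ring order of the response is shuffled `n_perm` times and PLS1 refit;
#' `p = (1 + #{permuted varexp >= observed}) / (n_perm + 1)`.
#'
#' @param fit a [fit_pls1()] result.
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @return list: `p`, `observed`, `n_perm`, `perm_varexp`.
#' @export
permute_varexp <- function(fit, n_perm = 10000, seed = 1) {
  stopifnot(inherits(fit, "pls1_fit"))
  if (n_perm < 100) stop_pv("n_perm must be >= 100",
                            class = "pvgrad_validation_error")
  n <- nrow(fit$X_std)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- fit$y_centred[sample.int(n)]
      .pls1_core(fit$X_std, yp - mean(yp))$varexp
    }, 1)
  })
  list(p = (1 + sum(perm >= fit$varexp)) / (n_perm + 1),
       observed = fit$varexp, n_perm = n_perm, perm_varexp = perm)
}

#' Bootstrap gene Z-scores for PLS1 weights
#'
#' Rings (the observation rows) are resampled with replacement and PLS1
#' refit on each resample; resampled weight vectors are sign-aligned to the
#' original (flipped when their correlation with the original weights is
#' negative) to remove component sign indeterminacy. The per-gene bootstrap
#' SE is the SD of the aligned resampled weights; `Z = weight / SE`, the
#' two-sided p comes from the standard normal and q from Benjamini-Hochberg.
#' Resamples with a near-constant response or fewer than `min_unique_rings`
#' distinct rings are redrawn; more than 50% redraws aborts.
#'
#' With few rings the bootstrap SE is itself noisy, which makes the null
#' distribution of Z markedly heavier-tailed than the standard normal; a
#' normal reference then yields anticonservative FDR. The default reference
#' is therefore a t distribution with (number of rings - 2) degrees of
#' freedom, matching the effective sample size behind the SE; `p_reference =
#' "normal"` restores the plain normal p.
#'
#' @param fit a [fit_pls1()] result.
#' @param n_boot bootstrap draws (>= 100).
#' @param seed integer seed.
#' @param min_unique_rings minimum distinct rings per resample.
#' @param p_reference null reference for the two-sided gene p: `"t"`
#'   (default, df = rings - 2) or `"normal"`.
#' @return data.frame of class `pls_gene_result`: `gene, weight, boot_se, z,
#'   p, q`, with the number of redraws as attribute `n_redraw`.
#' @export
bootstrap_gene_z <- function(fit, n_boot = 1000, seed = 1,
                             min_unique_rings = 5,
                             p_reference = c("t", "normal")) {
  p_reference <- match.arg(p_reference)
  stopifnot(inherits(fit, "pls1_fit"))
  if (n_boot < 100) stop_pv("n_boot must be >= 100",
                            class = "pvgrad_validation_error")
  n <- nrow(fit$X_std)
  W <- matrix(NA_real_, n_boot, ncol(fit$X_std))
  n_redraw <- 0L
  with_seed(seed, {
    for (bb in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- fit$y_centred[idx]
        if (length(unique(idx)) >= min_unique_rings && sd(yb) > 1e-12) break
        n_redraw <- n_redraw + 1L
        if (n_redraw > 0.5 * n_boot) {
          stop_pv("bootstrap instability: > 50% of resamples degenerate",
                  class = "pvgrad_instability_error")
        }
      }
      wb <- .pls1_core(fit$X_std[idx, , drop = FALSE], yb - mean(yb))$weights
      if (sum(wb * fit$weights) < 0) wb <- -wb
      W[bb, ] <- wb
    }
  })
  se <- apply(W, 2, sd)
  z <- fit$weights / se
  p <- if (p_reference == "t") 2 * pt(-abs(z), df = max(1, n - 2))
       else 2 * pnorm(-abs(z))
  out <- data.frame(gene = colnames(fit$X_std), weight = fit$weights,
                    boot_se = se, z = z, p = p, q = fdr_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_redraw") <- n_redraw
  class(out) <- c("pls_gene_result", class(out))
  out
}

#' Select gradient-associated gene lists (PLS1- / PLS1+)
#'
#' Genes enter PLS1+ when `Z > z_threshold` and `q < q_threshold`, PLS1-
#' when `Z < -z_threshold` and `q < q_threshold`; both lists are sorted by
#' `|Z|` descending.
#'
#' @param result a [bootstrap_gene_z()] table.
#' @param z_threshold absolute Z cutoff (default 5).
#' @param q_threshold FDR q cutoff (default 0.001, i.e. 1 per mille).
#' @return list with character vectors `pls1_neg` and `pls1_pos`.
#' @export
select_genes <- function(result, z_threshold = 5, q_threshold = 0.001) {
  pick <- function(cond) {
    sel <- result[cond & !is.na(result$z) & !is.na(result$q), , drop = FALSE]
    sel$gene[order(-abs(sel$z))]
  }
  list(pls1_neg = pick(result$z < -z_threshold & result$q < q_threshold),
       pls1_pos = pick(result$z > z_threshold & result$q < q_threshold))
}

#' Overlaps between gene lists across groups
#'
#' @param lists named list of character vectors (>= 2).
#' @return list: `pairwise` data.frame (`list1, list2, n1, n2, overlap,
#'   jaccard`), `global` character vector of genes common to all lists,
#'   `pair_genes` the per-pair intersections.
#' @export
overlap_lists <- function(lists) {
  if (length(lists) < 2) stop_pv("need >= 2 lists",
                                 class = "pvgrad_validation_error")
  nm <- names(lists)
  pairs <- utils::combn(nm, 2)
  pair_genes <- list()
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    l1 <- lists[[pairs[1, j]]]; l2 <- lists[[pairs[2, j]]]
    ov <- intersect(l1, l2)
    un <- union(l1, l2)
    pair_genes[[paste(pairs[, j], collapse = "&")]] <<- ov
    data.frame(list1 = pairs[1, j], list2 = pairs[2, j],
               n1 = length(l1), n2 = length(l2), overlap = length(ov),
               jaccard = if (length(un)) length(ov) / length(un) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(pairwise = do.call(rbind, rows),
       global = Reduce(intersect, lists),
       pair_genes = pair_genes)
}

#' Hypergeometric cell-type enrichment of a gene list
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' each cell-type set: `p = P(overlap >= observed)` with the universe as
#' population, the (universe-intersected) set as successes and the list as
#' draws; q by Benjamini-Hochberg across sets.
#'
#' @param gene_list character vector, must be contained in `universe`.
#' @param gene_sets named list of character vectors (e.g. read from GMT).
#' @param universe character vector of all testable genes.
#' @return data.frame of class `enrichment_result`: `set, universe_size,
#'   list_size, set_size, overlap, p, q`.
#' @export
celltype_enrichment <- function(gene_list, gene_sets, universe) {
  extra <- setdiff(gene_list, universe)
  if (length(extra)) {
    stop_pv("genes outside universe: ",
            paste(head(extra, 5), collapse = ", "),
            class = "pvgrad_validation_error")
  }
  N <- length(unique(universe))
  k <- length(unique(gene_list))
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(gene_list, s))
    p <- phyper(ov - 1, length(s), N - length(s), k, lower.tail = FALSE)
    data.frame(set = nm, universe_size = N, list_size = k,
               set_size = length(s), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  class(out) <- c("enrichment_result", class(out))
  out
}
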