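default_atlas <- function(n = 10) build_rings(array(0, c(1, 1, 1)), 3, n)

test_that("aggregate_expression_by_ring groups samples by distance bounds", {
  atlas <- default_atlas()
  samples <- data.frame(sample = c("a", "b", "c", "d", "e"),
                        distance_mm = c(4, 5, 33.0, 32.99, 7),
                        g1 = c(1, 3, 100, 7, 5), g2 = c(0, 1, 100, 2, 4))
  # need >= 3 populated rings: add two more samples
  samples <- rbind(samples,
                   data.frame(sample = "f", distance_mm = 10, g1 = 2, g2 = 2))
  rx <- aggregate_expression_by_ring(samples, atlas)
  expect_equal(rx$X["1", "g1"], 2)          # samples at 4 and 5 mm -> ring 1
  expect_false("11" %in% rownames(rx$X))    # 33.0 mm is out of the design
  expect_equal(rx$X["10", "g1"], 7)         # 32.99 mm -> ring 10
  expect_equal(unname(rx$n_samples["1"]), 2L)

  # brute-force group-by oracle on a random table
  set.seed(40)
  tab <- data.frame(distance_mm = runif(60, 0, 36),
                    g1 = rnorm(60), g2 = rnorm(60))
  rx2 <- aggregate_expression_by_ring(tab, atlas)
  oracle_ring <- ifelse(tab$distance_mm >= 3 & tab$distance_mm < 33,
                        floor((tab$distance_mm - 3) / 3) + 1, NA)
  for (k in rownames(rx2$X)) {
    sel <- !is.na(oracle_ring) & oracle_ring == as.integer(k)
    expect_equal(unname(rx2$X[k, "g1"]), mean(tab$g1[sel]))
    expect_equal(unname(rx2$X[k, "g2"]), mean(tab$g2[sel]))
  }

  expect_error(aggregate_expression_by_ring(
    data.frame(distance_mm = c(4, 5), g1 = 1:2), atlas),
    class = "pvgrad_insufficient_data_error")
})

test_that("fit_pls1 finds the informative gene and obeys symmetries", {
  set.seed(7)
  y <- rnorm(10)
  X <- matrix(rnorm(10 * 50), 10, 50,
              dimnames = list(NULL, sprintf("g%02d", 1:50)))
  X[, 7] <- as.numeric(scale(y))
  fit <- fit_pls1(X, y)
  expect_equal(which.max(abs(fit$weights)), 7, ignore_attr = TRUE)
  expect_gt(fit$varexp, 0.95)
  expect_equal(sqrt(sum(fit$weights^2)), 1, tolerance = 1e-12)
  expect_true(fit$varexp >= 0 && fit$varexp <= 1)

  # antisymmetric gene pair gets equal-magnitude opposite weights
  X2 <- cbind(X, gneg = -X[, 7])
  fit2 <- fit_pls1(X2, y)
  expect_equal(fit2$weights[["g07"]], -fit2$weights[["gneg"]])

  # positive rescaling of a gene column changes nothing
  X3 <- X; X3[, 3] <- X[, 3] * 37
  fit3 <- fit_pls1(X3, y)
  expect_equal(fit3$weights, fit$weights, tolerance = 1e-12)

  expect_error(fit_pls1(X, rep(1, 10)),
               class = "pvgrad_degenerate_response_error")
})

test_that("fit_pls1 agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(42)
  X <- matrix(rnorm(12 * 30), 12, 30,
              dimnames = list(NULL, sprintf("g%02d", 1:30)))
  y <- rnorm(12)
  fit <- fit_pls1(X, y)
  mo <- mixOmics::pls(X, y, ncomp = 1, scale = TRUE, mode = "regression")
  w_mo <- mo$loadings$X[, 1]
  expect_gt(abs(cor(fit$weights, w_mo)), 1 - 1e-10)
})

test_that("permute_varexp respects the add-one bound and null behaviour", {
  set.seed(43)
  X <- matrix(rnorm(10 * 40), 10, 40,
              dimnames = list(NULL, sprintf("g%02d", 1:40)))
  y <- rnorm(10)
  fit <- fit_pls1(X, y)
  pm <- permute_varexp(fit, n_perm = 100, seed = 44)
  expect_gte(pm$p, 1 / 101)
  expect_lte(pm$p, 1)
  expect_error(permute_varexp(fit, n_perm = 10),
               class = "pvgrad_validation_error")
  # determinism
  pm2 <- permute_varexp(fit, n_perm = 100, seed = 44)
  expect_identical(pm$perm_varexp, pm2$perm_varexp)
})

test_that("bootstrap Z flips sign with the response and flags associations", {
  y <- 0.02 * (1:10)
  ex <- make_expression(expression_spec(n_genes = 300, n_associated = 30,
                                        effect_size = 1, noise_sd = 0.1,
                                        samples_per_ring = 3, seed = 45), y)
  rx <- aggregate_expression_by_ring(ex$samples, default_atlas())
  fit <- fit_pls1(rx, y)
  gz <- bootstrap_gene_z(fit, n_boot = 300, seed = 46)
  flip <- bootstrap_gene_z(fit_pls1(rx, -y), n_boot = 300, seed = 46)
  expect_equal(gz$z, -flip$z)

  assoc <- gz$gene %in% ex$truth$gene[ex$truth$associated]
  expect_gte(mean(abs(gz$z[assoc]) > 5), 0.9)
  expect_lt(mean(abs(gz$z[!assoc]) > 5), 0.02)
  # sign of Z tracks the generating sign for associated genes
  sgn <- ex$truth$sign[match(gz$gene[assoc], ex$truth$gene)]
  expect_gt(mean(sign(gz$z[assoc]) == sgn), 0.95)
})

test_that("select_genes applies the Z and q thresholds conjunctively", {
  res <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    weight = 1, boot_se = 1,
                    z = c(6, -7, 4.9, 5.5, -6),
                    q = c(1e-5, 1e-5, 1e-9, 0.01, 5e-4))
  sel <- select_genes(res)
  expect_identical(sel$pls1_pos, "a")
  expect_identical(sel$pls1_neg, c("b", "e"))   # sorted by |Z| descending
  empty <- select_genes(res[0, ])
  expect_length(empty$pls1_pos, 0)
  expect_length(empty$pls1_neg, 0)
})

test_that("overlap_lists matches brute-force set arithmetic", {
  l <- list(a = c("x", "y", "z"), b = c("x", "y", "z"), c = c("p", "q"))
  ov <- overlap_lists(l)
  ab <- ov$pairwise[ov$pairwise$list1 == "a" & ov$pairwise$list2 == "b", ]
  expect_equal(ab$jaccard, 1)
  ac <- ov$pairwise[ov$pairwise$list1 == "a" & ov$pairwise$list2 == "c", ]
  expect_equal(ac$jaccard, 0)
  set.seed(47)
  rl <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
  names(rl) <- c("g1", "g2", "g3")
  ov2 <- overlap_lists(rl)
  for (j in seq_len(nrow(ov2$pairwise))) {
    row <- ov2$pairwise[j, ]
    expect_equal(row$overlap,
                 length(intersect(rl[[row$list1]], rl[[row$list2]])))
  }
  expect_identical(ov2$global, Reduce(intersect, rl))
})

test_that("celltype_enrichment matches exact hypergeometric enumeration", {
  universe <- paste0("g", 1:10)
  gene_list <- universe[1:4]
  sets <- list(s5 = universe[c(1:4, 8)], all = universe,
               none = universe[9:10])
  enr <- celltype_enrichment(gene_list, sets, universe)
  expect_equal(enr$p[enr$set == "s5"], 5 / 210)
  expect_equal(enr$p[enr$set == "all"], 1)       # set = universe
  expect_equal(enr$p[enr$set == "none"], 1)      # zero overlap
  expect_true(all(enr$overlap <= pmin(enr$list_size, enr$set_size)))

  expect_error(celltype_enrichment(c("g1", "zz"), sets, universe),
               class = "pvgrad_validation_error")

  # random configurations vs the enumeration oracle
  set.seed(48)
  for (i in 1:20) {
    N <- sample(5:20, 1)
    uni <- paste0("u", seq_len(N))
    k <- sample(1:N, 1)
    s <- sample(uni, sample(1:N, 1))
    gl <- sample(uni, k)
    e <- celltype_enrichment(gl, list(s = s), uni)
    expect_equal(e$p, hyper_upper_oracle(e$overlap, length(s), N, k))
  }
})
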