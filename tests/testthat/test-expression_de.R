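test_that("percentile-shift normalization pins every sample's quantile at zero", {
  const <- matrix(5, 10, 4)
  expect_true(all(percentile_shift_normalize(const) == 0))

  set.seed(2)
  m <- matrix(rnorm(200 * 12, 8, 2), 200, 12)
  norm <- percentile_shift_normalize(m)
  q75 <- apply(norm, 2, quantile, probs = 0.75, names = FALSE)
  expect_equal(q75, rep(0, 12), tolerance = 1e-12)

  # adding a constant to one sample's column is undone exactly
  m2 <- m
  m2[, 3] <- m2[, 3] + 1.7
  expect_equal(percentile_shift_normalize(m2), norm)
})

test_that("the per-gene test reduces to the classical pooled t and degenerates sanely", {
  x <- c(1.2, 1.4, 1.1, 1.3)
  expect_equal(test_gene(x, x)$p, 1)
  expect_equal(test_gene(x, x)$log2fc, 0)

  set.seed(5)
  for (i in 1:200) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    got <- test_gene(a, b, moderated = FALSE)
    ref <- t.test(b, a, var.equal = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  }

  # moderation shrinks extreme variances toward the prior and adds df
  lowvar <- test_gene(c(1, 1.001, 0.999), c(2, 2.001, 1.999),
                      moderated = TRUE, prior_var = 1)
  plain <- test_gene(c(1, 1.001, 0.999), c(2, 2.001, 1.999), moderated = FALSE)
  expect_gt(lowvar$p, plain$p)
  expect_equal(lowvar$df, plain$df + 4)

  # both groups constant and equal -> p = 1
  expect_equal(test_gene(c(2, 2), c(2, 2))$p, 1)
})

test_that("BH adjustment equals the step-up oracle and is monotone above raw p", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("fold-change classification applies the signed 1.3-fold convention", {
  expect_equal(classify_de(-1.0, 0.01), "decreased")
  expect_equal(classify_de(-1.0, 0.20), "tending_decreased")
  expect_equal(classify_de(-0.1, 0.001), "unchanged")
  expect_equal(classify_de(1.0, 0.01), "increased")
  expect_equal(classify_de(0.5, 0.20), "unchanged")  # up but not significant
  # the threshold itself qualifies
  expect_equal(classify_de(-log2(1.3), 0.01), "decreased")
})

test_that("distance correlation recovers exact and simulated relationships", {
  d <- tibble::tibble(log2fc = seq(0, 2, length.out = 10) * 0.5,
                      distance_bp = seq(0, 3e6, length.out = 10))
  expect_equal(distance_correlation(d)$r, 1)

  expect_warning(
    flat <- distance_correlation(tibble::tibble(log2fc = rep(1, 5),
                                                distance_bp = 1:5)),
    "zero variance")
  expect_true(is.na(flat$r))

  # noise-free graded knockdown: r equals the generator's closed form to 1e-12
  sim <- simulate_cluster_expression(n_genes = 100, noise_sd_log2 = 0, seed = 13)
  res <- de_analyze(sim$intensities, sim$groups, sim$genes, sim$element)
  expect_equal(res$summary$distance_r, sim$expected_r, tolerance = 1e-12)

  # distance-independent effects: r within the null envelope
  null <- simulate_cluster_expression(n_genes = 300, max_knockdown_log2 = 0,
                                      seed = 14)
  rn <- de_analyze(null$intensities, null$groups, null$genes, null$element)
  expect_lt(abs(rn$summary$distance_r), 3 / sqrt(300))
})

test_that("ISH fold changes behave at the boundaries and track array fold changes", {
  expect_equal(ish_fold_change(c(10, 10), c(10, 10))$fold_change, 1)
  expect_equal(ish_fold_change(rep(0, 5), c(8, 12))$fold_change, 0)
  expect_warning(undef <- ish_fold_change(c(5, 5), c(0, 0)), "zero")
  expect_true(is.na(undef$fold_change))

  # agreement design: per-gene ISH and array log2FCs share a common truth
  withr::with_seed(42, {
    true_fc <- runif(18, -3, 0.3)
    array_fc <- true_fc + rnorm(18, 0, 0.3)
    ish_fc <- vapply(true_fc, function(f) {
      wt <- rnorm(5, 100, 10)
      mut <- rnorm(5, 100 * 2^f, 10 * 2^f)
      ish_fold_change(mut, pmax(wt, 1))$log2fc
    }, numeric(1))
    r <- cor(array_fc, ish_fc)
    r_truth <- cor(array_fc, true_fc)
    expect_gt(r, 0.8)
    expect_lt(abs(r - r_truth), 0.15)
  })
})

test_that("the full DE analysis is shift-invariant and directionally correct", {
  sim <- simulate_cluster_expression(n_genes = 120, seed = 19)
  res <- de_analyze(sim$intensities, sim$groups, sim$genes, sim$element)

  # per-sample additive shifts are absorbed by normalization
  shifted <- sweep(sim$intensities, 2, rnorm(ncol(sim$intensities), 0, 2), "+")
  res2 <- de_analyze(shifted, sim$groups, sim$genes, sim$element)
  expect_equal(res$calls$p, res2$calls$p, tolerance = 1e-9)
  expect_equal(res$calls$log2fc, res2$calls$log2fc, tolerance = 1e-9)

  # knockdown is detected predominantly as decreases, graded with distance
  calls <- tidy(res)
  proximal <- calls[calls$distance_bp < 1e6, ]
  distal <- calls[calls$distance_bp > 2e6, ]
  expect_gt(mean(proximal$category == "decreased"),
            mean(distal$category == "decreased"))
  expect_gt(res$summary$distance_r, 0)
  expect_true(all(calls$p_adj >= calls$p))

  gl <- glance(res)
  expect_equal(gl$n_genes, 120)
  expect_equal(gl$n_decreased + gl$n_increased + gl$n_tending_decreased +
                 gl$n_unchanged, 120)
})
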