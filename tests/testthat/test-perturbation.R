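test_that("differential activity: identical conditions give null results", {
  withr::with_seed(3, {
    m <- matrix(runif(10 * 5), 10, 5); colnames(m) <- seq(2, 10, 2)
  })
  da <- differential_activity(m, m)
  expect_equal(da$table$effect, rep(0, 5))
  # zero effect with pooled variance > 0 gives p = 1
  expect_true(all(da$table$p == 1 | is.na(da$table$p)))
  expect_equal(da$transcriptional_difference, 0)
  expect_error(differential_activity(m[1:2, ], m), "at least 3")
  expect_error(differential_activity(m, m[, 1:3]), "different TU sets")
})

test_that("a 2-sd mean shift at n = 50 per arm is detected almost surely", {
  # closed-form power of the two-sample t-test at delta = 0.2, sd = 0.1,
  # n = 50/arm is > 0.99; the empirical detection rate should match
  withr::with_seed(11, {
    n_tu <- 200
    a <- matrix(rnorm(50 * n_tu, 0.5, 0.1), 50, n_tu)
    b <- matrix(rnorm(50 * n_tu, 0.7, 0.1), 50, n_tu)
    colnames(a) <- colnames(b) <- seq_len(n_tu)
    da <- differential_activity(a, b)
    expect_gt(mean(da$table$p < 0.05), 0.99)
    expect_equal(mean(da$table$effect), 0.2, tolerance = 0.05)
  })
})

test_that("transcriptional difference is a metric and respects exclusion", {
  a <- c(`1` = 0.5, `2` = 0.2, `3` = 0.9)
  b <- c(`1` = 0.5, `2` = 0.5, `3` = 0.9)
  expect_equal(transcriptional_difference(a, a), 0)
  expect_equal(transcriptional_difference(a, b), 0.3)
  expect_equal(transcriptional_difference(a, b, exclude_index = 2), 0)
  expect_error(transcriptional_difference(a, b[1:2]), "length")
  # metric axioms on random triples
  withr::with_seed(13, {
    for (k in 1:20) {
      x <- runif(6); y <- runif(6); z <- runif(6)
      dxy <- transcriptional_difference(x, y)
      dyx <- transcriptional_difference(y, x)
      expect_equal(dxy, dyx)
      expect_lte(transcriptional_difference(x, z),
                 dxy + transcriptional_difference(y, z) + 1e-12)
      expect_gte(dxy, 0)
    }
  })
})

test_that("knockout sweep covers every TU of a small fibre", {
  fib <- build_toy_fibre(M = 80, n_tu = 5, seed = 17)
  cfg <- sim_config(n_tf = 4, t_pushoff = 20, t_equil = 50, t_prod = 300,
                    sample_interval = 50)
  wt <- per_run_activity(simulate_ensemble(fib, cfg, n_runs = 4,
                                           base_seed = 40))
  sweep <- knockout_sweep(fib, cfg, wt_runs = wt, base_seed = 40)
  expect_equal(nrow(sweep), 5)
  expect_equal(sweep$tu_index, tu_indices(fib))
  expect_true(all(sweep$transcriptional_difference >= 0))
})

test_that("Manhattan and QQ series: degenerate and uniform nulls", {
  tab <- data.frame(tu_index = 1:50, activity_a = 0.5, activity_b = 0.5,
                    effect = 0, t = 0, p = rep(1, 50))
  res <- structure(list(table = tab), class = "perturbation_result")
  pos <- data.frame(tu_index = 1:50, pos = (1:50) * 3e4)
  mq <- manhattan_qq(res, pos)
  expect_equal(mq$manhattan$neglog10p, rep(0, 50))
  expect_equal(mq$manhattan$pos_mbp, (1:50) * 0.03)
  # uniform p-values sit on the identity line of the QQ plot
  withr::with_seed(19, {
    tab$p <- runif(50)
    res$table <- tab
    qq <- manhattan_qq(res, pos)$qq
    # compare in p-space via the KS statistic of uniformity
    ks <- suppressWarnings(stats::ks.test(tab$p, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_lt(max(abs(10^-qq$observed - 10^-qq$expected)), 0.2)
  })
  expect_error(manhattan_qq(res, pos[1:10, ]), "missing genomic positions")
})

test_that("deleting a TU-rich region raises activity of surviving TUs", {
  # fewer TUs compete for the same TFs, so the survivors gain activity
  fib <- build_toy_fibre(M = 300, n_tu = 24, seed = 23)
  cfg <- sim_config(n_tf = 8, t_pushoff = 50, t_equil = 150, t_prod = 600,
                    sample_interval = 50)
  tus <- tu_indices(fib)
  inside <- tus[tus >= 100 & tus <= 220]
  expect_gt(length(inside), 3)             # the cut really removes TUs
  del <- delete_region(fib, 100, 220)
  wt <- per_run_activity(simulate_ensemble(fib, cfg, n_runs = 6,
                                           base_seed = 60))
  mut <- per_run_activity(simulate_ensemble(del, cfg, n_runs = 6,
                                            base_seed = 60))
  surviving <- setdiff(tus, 100:220)
  new_idx <- ifelse(surviving > 220, surviving - 121L, surviving)
  wt_mean <- colMeans(wt)[as.character(surviving)]
  mut_mean <- colMeans(mut)[as.character(new_idx)]
  expect_gt(mean(mut_mean - wt_mean), 0)
})
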