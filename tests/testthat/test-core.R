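test_that("pairing enumerates the control-major grid deterministically", {
  p <- build_pairing(2, 2)
  expect_identical(unname(p),
                   cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L)))
  expect_equal(nrow(build_pairing(10, 10)), 100L)
  # a partial pairing is the prefix of the full grid
  full <- build_pairing(3, 2)
  expect_identical(build_pairing(3, 2, k = 5), full[1:5, ])
  expect_error(build_pairing(3, 2, k = 0), "'k'")
  expect_error(build_pairing(3, 2, k = 7), "'k'")
})

test_that("pairwise log2 fold changes are per-pair differences", {
  vals <- rbind(g1 = c(10, 10, 10, 10), g2 = c(10, 12, 11, 9))
  colnames(vals) <- paste0("s", 1:4)
  es <- expression_set(vals, control = 1:2, test = 3:4)
  fc <- pairwise_log_fc(es)
  expect_equal(unname(fc["g1", ]), rep(0, 4))       # ratio 1 <=> log-FC 0
  expect_equal(unname(fc["g2", ]), c(1, -1, -1, -3)) # (c1,t1)(c1,t2)(c2,t1)(c2,t2)

  es1 <- expression_set(rbind(a = c(10, 11), b = c(5, 4)),
                        control = 1, test = 2)
  expect_equal(unname(pairwise_log_fc(es1)[, 1]), c(1, -1))
})

test_that("the bundled two-gene example reproduces its per-pair fold change", {
  es <- two_gene_example()
  fc <- pairwise_log_fc(es, build_pairing(10, 10))
  expect_equal(unname(fc["MACF1", 1]), 11.0375 - 11.1435) # = -0.1060
})

test_that("column ranks match the count-based midrank oracle and conserve sums", {
  expect_equal(unname(rank_columns(cbind(c(0.5, -1, 2)))[, 1]), c(2, 1, 3))
  expect_equal(unname(rank_columns(cbind(c(1, 1, 3)))[, 1]), c(1.5, 1.5, 3))
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:200, 1)
    col <- sample(rnorm(n %/% 2 + 1), n, replace = TRUE)  # forces ties
    r <- rank_columns(cbind(col))[, 1]
    expect_equal(r, brute_midranks(col))
    expect_equal(sum(r), n * (n + 1) / 2)
  }
  expect_error(rank_columns(cbind(c(1, NA, 2))), "finite")
})

test_that("trimmed rank means agree with the sort-slice-mean oracle", {
  n <- 10
  ranks <- matrix(c(1, 2, 3, 4, 5), nrow = 1)
  ranks <- ranks[rep(1, n), ] + 0  # n genes so standardization is by n
  expect_equal(unname(trimmed_rank_means(ranks, trim = 0.2)), rep(3 / n, n))
  # constant rank vector: any valid trim returns r / n
  const <- matrix(7, nrow = n, ncol = 6)
  expect_equal(unname(trimmed_rank_means(const, trim = 0.3)), rep(7 / n, n))

  set.seed(202)
  rk <- matrix(sample(1:200, 200 * 9, replace = TRUE), nrow = 200)
  got <- trimmed_rank_means(rk, trim = 0.3)
  want <- apply(rk, 1, brute_trimmed_mean, trim = 0.3) / 200
  expect_equal(unname(got), want)
  expect_error(trimmed_rank_means(rk, trim = 0.6), "trim")
})

test_that("rank model recovers the closed-form summary of an ideal grid", {
  n <- 100
  rbar <- (1:n) / n
  fit <- fit_rank_model(rbar)
  expect_equal(fit$a, 1 / n)
  expect_equal(fit$b, 1)
  expect_equal(fit$delta_hat, 1 / n)
  expect_equal(fit$R_bar, (n + 1) / (2 * n))
  expect_equal(fit$sigma2_hat, var((1:n)) / n^2)
  expect_error(fit_rank_model(rep(0.5, 10)), "degenerate")
  expect_error(fit_rank_model(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("delta_hat equals the mean of consecutive sorted gaps (telescoping)", {
  set.seed(303)
  for (i in 1:100) {
    rbar <- runif(sample(5:500, 1), min = 1e-6, max = 1)
    fit <- fit_rank_model(rbar)
    expect_equal(fit$delta_hat, mean(diff(sort(rbar))), tolerance = 1e-12)
  }
})

test_that("f-values follow the fitted normal model", {
  set.seed(7)
  rbar <- runif(200, 0.01, 1)
  fit <- fit_rank_model(rbar)
  f <- f_values(rbar, fit)
  expect_true(all(f > 0 & f < 1))
  expect_equal(unname(f_values(fit$R_bar, fit)), 0.5)
  expect_equal(unname(f_values(fit$R_bar + 1.959964 * sqrt(fit$sigma2_hat), fit)),
               0.975, tolerance = 1e-6)
})

test_that("a gene dominating every comparison gets the maximal f-value", {
  es <- random_es(n = 100, m1 = 3, m2 = 3, seed = 9, sd = 0.3)
  es$values[17, es$test] <- es$values[17, es$test] + 50  # beats all log-FCs
  fit <- fcros(es)
  expect_equal(which.max(fit$results$f_value), 17L)
})

test_that("classification thresholds partition genes and set the error", {
  f <- c(0.01, 0.3, 0.5, 0.99, 0.025, 0.975)
  cls <- classify_genes(f, alpha1 = 0.025, alpha2 = 0.975)
  expect_equal(as.character(cls$call),
               c("down", "EE", "EE", "up", "down", "up"))
  expect_equal(cls$error_percent, 5)
  expect_error(classify_genes(f, 0.5, 0.4), "alpha")
  expect_error(selection_error(0.9, 0.1), "alpha")
})

test_that("theoretical moments match brute-force enumeration of spaced grids", {
  expect_equal(theoretical_moments(1, 2, 2, 1),
               c(mean = 1.5, variance = 0.25))
  set.seed(404)
  for (i in 1:20) {
    n <- sample(2:1000, 1)
    a <- runif(1, 0, 5); delta <- runif(1, 0, 2)
    grid <- a + (0:(n - 1)) * delta
    tm <- theoretical_moments(a, max(grid), n, delta)
    expect_equal(unname(tm["mean"]), mean(grid))
    expect_equal(unname(tm["variance"]), mean((grid - mean(grid))^2))
  }
  # ideal case a = delta = 1, b = n
  n <- 50
  expect_equal(unname(theoretical_moments(1, n, n, 1)),
               c((n + 1) / 2, (n^2 - 1) / 12))
})

test_that("fcros recovers planted up- and down-shifted genes", {
  es <- random_es(n = 500, m1 = 5, m2 = 5, seed = 21, sd = 0.3)
  up <- 1:10; down <- 11:20
  es$values[up, es$test] <- es$values[up, es$test] + 3
  es$values[down, es$test] <- es$values[down, es$test] - 3
  fit <- fcros(es)
  f <- coef(fit)
  expect_setequal(order(f, decreasing = TRUE)[1:10], up)
  expect_setequal(order(f)[1:10], down)
  expect_true(all(fit$results$call[up] == "up"))
  expect_true(all(fit$results$call[down] == "down"))
  # one strongly shifted gene against a flat background tops the list
  flat <- random_es(n = 50, m1 = 3, m2 = 3, seed = 5, sd = 0.1)
  flat$values[30, flat$test] <- flat$values[30, flat$test] + 3
  expect_equal(which.max(coef(fcros(flat)))[[1]], 30L)
})

test_that("fcros object exposes the standard accessors", {
  es <- random_es(n = 40, seed = 3)
  fit <- fcros(es)
  expect_s3_class(fit, "fcros")
  expect_named(as.data.frame(fit),
               c("gene_id", "rbar", "f_value", "fold_change", "call"))
  expect_length(coef(fit), 40)
  expect_output(print(fit), "FCROS fit")
  expect_output(print(summary(fit)), "delta_hat")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})

test_that("fcros2 on a duplicated batch preserves the single-batch ordering", {
  # k = 10 with trim 0.3: the cut count (3) doubles exactly (6) when the
  # rank set is duplicated, so trimmed means are unchanged
  es <- random_es(n = 120, m1 = 5, m2 = 2, seed = 31)
  one <- fcros(es)
  two <- fcros2(es, es)
  expect_equal(two$k, 2 * one$k)
  expect_equal(two$results$rbar, one$results$rbar)
  expect_equal(order(two$results$f_value), order(one$results$f_value))
})

test_that("fcros2 is invariant to a constant batch offset", {
  es <- random_es(n = 120, m1 = 5, m2 = 2, seed = 31)
  shifted <- expression_set(es$values + 5, control = es$control,
                            test = es$test)
  expect_equal(fcros2(es, shifted)$results$f_value,
               fcros2(es, es)$results$f_value)
})

test_that("fcros2 recovers DE genes planted in two independent batches", {
  b <- simulate_two_batches(n = 400, m1 = 4, m2 = 4, p_de = 0.05,
                            sigma_n = 0.2, seed = 61, batch_shift = 3,
                            seed2 = 62)
  fit <- fcros2(b$batch1$data, b$batch2$data)
  truth <- seq_len(400) %in% b$batch1$de_indices
  expect_gt(rank_auc(de_score(coef(fit)), truth), 0.95)
})

test_that("fcros2 rejects mismatched gene sets with a located diagnostic", {
  es <- random_es(n = 10, seed = 1)
  other <- es
  rownames(other$values)[4] <- "different"
  expect_error(fcros2(es, other), "row 4")
})

test_that("fold changes reproduce doubling and identity cases", {
  vals <- rbind(a = c(3, 3, 4, 4), b = c(6, 8, 6, 8))
  colnames(vals) <- paste0("s", 1:4)
  es <- expression_set(vals, control = 1:2, test = 3:4)
  fc <- fold_changes(es)
  expect_equal(unname(fc["a"]), 2)   # doubled on unlogged scale
  expect_equal(unname(fc["b"]), 1)   # identical groups
  # log2-ratio data always use the geometric form
  es2 <- expression_set(vals, control = 1:2, test = 3:4,
                        scale = "log2-ratio")
  expect_equal(unname(fold_changes(es2)["a"]), 2^1)
  expect_equal(unname(fold_changes(es, "geometric")),
               unname(fold_changes(es2)))
})

test_that("expression set validation catches malformed input", {
  m <- matrix(1:8 + 0, nrow = 2, dimnames = list(c("a", "b"), NULL))
  expect_error(expression_set(m, control = 1:2, test = 2:3), "disjoint")
  expect_error(expression_set(m, control = 1:2, test = 3:4,
                              gene_ids = c("x", "x")), "duplicated gene id")
  m[1, 3] <- NA
  expect_error(expression_set(m, control = 1:2, test = 3:4), "non-finite")
})
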