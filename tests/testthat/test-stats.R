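test_that("category enrichment builds 2x2 tables with OR, Fisher p and BH q", {
  # planted: 30/10 in-category vs 50/50 outside -> OR = 3
  gene_table <- tibble::tibble(
    gene = sprintf("g%03d", 1:140),
    category = rep(c("endocrine", "other"), c(40L, 100L)),
    is_match = c(rep(c(TRUE, FALSE), c(30L, 10L)),
                 rep(c(TRUE, FALSE), c(50L, 50L)))
  )
  enr <- category_enrichment(gene_table)
  row <- enr[enr$category == "endocrine", ]
  expect_equal(row$odds_ratio, 3)
  expect_equal(unlist(row[, c("a", "b", "c", "d")], use.names = FALSE),
               c(30L, 10L, 50L, 50L))
  expect_equal(row$p_value, oracle_fisher_p(30, 10, 50, 50))
  # identical proportions give OR 1 and p 1
  null_table <- tibble::tibble(
    gene = sprintf("g%03d", 1:80),
    category = rep(c("a", "b"), each = 40L),
    is_match = rep(c(TRUE, FALSE), 40L)
  )
  enr0 <- category_enrichment(null_table)
  expect_equal(enr0$odds_ratio, c(1, 1))
  expect_equal(enr0$p_value, c(1, 1))
  expect_error(category_enrichment(gene_table[gene_table$category ==
                                                "other", ]),
               "two categories")
})

test_that("BH q-values follow the step-up formula and stay in range", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(stats::p.adjust(p, "BH"), c(0.03, 0.03, 0.03))
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1L))
    q <- stats::p.adjust(p, "BH")
    expect_equal(q, oracle_bh(p))
    expect_true(all(q <= 1 & q >= 0))
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("enrichment q-values control the FDR under a global null", {
  # all categories share one match rate; expected false-discovery
  # proportion at q < 0.05 stays at or below 0.05
  set.seed(42)
  n_sim <- 120L
  fdp <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    gt <- tibble::tibble(
      gene = sprintf("g%03d", 1:300),
      category = sample(letters[1:6], 300L, replace = TRUE),
      is_match = runif(300L) < 0.5
    )
    enr <- category_enrichment(gt)
    fdp[s] <- as.numeric(any(enr$q_value < 0.05))
  }
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("count comparison reproduces exact rank-sum p-values", {
  # no shift: p at (or extremely near) 1
  expect_gte(compare_counts(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.99)
  # maximal separation at n = 3,3: exact two-sided p = 0.1
  expect_equal(compare_counts(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(oracle_wilcoxon_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # agreement with the exhaustive-permutation oracle on random untied sets
  set.seed(8)
  for (rep in 1:10) {
    x <- sample(1:50, 4L)
    y <- sample(51:100, 5L) - 25L
    if (length(intersect(x, y))) next
    expect_equal(compare_counts(x, y), oracle_wilcoxon_p(x, y))
  }
  # planted shift at n = 500/500 is overwhelming
  set.seed(9)
  expect_lt(compare_counts(rnorm(500), rnorm(500) + 1.5), 1e-6)
  expect_error(compare_counts(numeric(0), 1:3), "non-empty")
})

test_that("correlate validates its inputs and recovers planted correlation", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  expect_error(correlate(1:4, rep(2, 4)), "zero variance")
  expect_error(correlate(1:4, 1:5), "equal length")
  expect_error(correlate(1:2, 2:3), "at least 3")
  set.seed(10)
  n <- 10000L
  z <- rnorm(n)
  xx <- z + rnorm(n)
  yy <- z + rnorm(n) # rho = 0.5
  expect_lt(abs(correlate(xx, yy) - 0.5), 0.03)
})

test_that("logistic fit recovers a planted slope and flags degenerate input", {
  set.seed(11)
  n <- 5000L
  x <- rnorm(n)
  y <- runif(n) < plogis(-0.3 + 1.0 * x)
  tbl <- tibble::tibble(is_match = y, n_procedures = x)
  fit <- fit_match_model(tbl, features = "n_procedures")
  est <- fit$coefficients[fit$coefficients$term == "n_procedures", ]
  # covariate is standardised; x already ~N(0,1) so slope stays ~1
  expect_lt(abs(est$estimate * 1 / sd(x) - 1.0), 0.1)
  expect_true(fit$converged)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)

  expect_error(fit_match_model(tibble::tibble(is_match = rep(TRUE, 10L),
                                              n_procedures = rnorm(10L)),
                               features = "n_procedures"),
               "both classes")
  expect_error(fit_match_model(tibble::tibble(is_match = rep(c(TRUE, FALSE), 5L),
                                              n_procedures = rep(1, 10L)),
                               features = "n_procedures"),
               "constant")
  # complete separation is flagged, not silently reported
  sep <- tibble::tibble(is_match = rep(c(FALSE, TRUE), each = 50L),
                        n_procedures = c(rnorm(50L, -8), rnorm(50L, 8)))
  expect_error(fit_match_model(sep, features = "n_procedures"),
               "separation")
})

test_that("noise features give ~95% CI coverage of zero", {
  set.seed(12)
  n_rep <- 60L
  covered <- matrix(NA, n_rep, 2L)
  for (r in seq_len(n_rep)) {
    n <- 800L
    tbl <- tibble::tibble(
      is_match = runif(n) < 0.5,
      n_procedures = rnorm(n),
      n_hpo_terms = rpois(n, 8)
    )
    fit <- fit_match_model(tbl, features = c("n_procedures", "n_hpo_terms"))
    cf <- fit$coefficients[-1L, ]
    covered[r, ] <- cf$ci_low <= 0 & 0 <= cf$ci_high
  }
  # binomial slack around the 95% nominal level
  expect_gte(mean(covered), 0.95 - 3 * sqrt(0.05 * 0.95 / (2 * n_rep)))
})

test_that("coefficient bias shrinks as the sample grows", {
  set.seed(13)
  bias <- vapply(c(500L, 2000L, 8000L), function(n) {
    est <- vapply(1:8, function(r) {
      x <- rnorm(n)
      y <- runif(n) < plogis(0.2 + 0.8 * x)
      fit <- fit_match_model(tibble::tibble(is_match = y, n_mp_terms = x),
                             features = "n_mp_terms")
      fit$coefficients$estimate[2L] / sd(x)
    }, numeric(1L))
    abs(mean(est) - 0.8)
  }, numeric(1L))
  expect_lt(bias[3L], 0.05)
  expect_lt(bias[3L], bias[1L] + 0.05)
})

test_that("stats writers emit enrichment and regression tables", {
  gene_table <- tibble::tibble(
    gene = sprintf("g%03d", 1:100),
    category = sample(c("a", "b", "c"), 100L, replace = TRUE),
    is_match = runif(100L) < 0.5
  )
  enr <- category_enrichment(gene_table)
  set.seed(1)
  tbl <- tibble::tibble(is_match = runif(300L) < 0.5,
                        n_procedures = rnorm(300L))
  fit <- fit_match_model(tbl, features = "n_procedures")
  dir <- withr::local_tempdir()
  write_stats_outputs(enr, fit, dir)
  expect_true(file.exists(file.path(dir, "enrichment.tsv")))
  reg <- readr::read_tsv(file.path(dir, "regression.tsv"),
                         show_col_types = FALSE)
  expect_equal(reg$feature, c("(Intercept)", "n_procedures"))
})
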