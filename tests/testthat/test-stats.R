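# construct a sample with exactly the requested mean and SD
sample_with_moments <- function(m, s, n) {
  x <- seq_len(n)
  m + s * (x - mean(x)) / sd(x)
}

test_that("group summaries compute the t-based confidence interval", {
  const <- summarize_group(rep(3.5, 10))
  expect_equal(const$M, 3.5)
  expect_equal(const$MED, 3.5)
  expect_equal(const$SD, 0)
  expect_equal(const$CI_lower, 3.5)
  expect_equal(const$CI_upper, 3.5)

  s <- summarize_group(sample_with_moments(-64.94, 58.84, 25))
  expect_equal(s$CI_upper, -40.65, tolerance = 0.01)

  s2 <- summarize_group(sample_with_moments(-66.59, 92.73, 25))
  expect_equal(s2$CI_lower, -104.87, tolerance = 0.001)
  expect_equal(s2$CI_upper, -28.31, tolerance = 0.001)

  expect_error(summarize_group(1), "insufficient data")
  expect_true(s$MIN <= s$MED && s$MED <= s$MAX)
  expect_true(s$CI_lower <= s$M && s$M <= s$CI_upper)
})

test_that("normality tests are calibrated and detect bimodality", {
  set.seed(41)
  normal_ok <- vapply(1:200, function(i) {
    res <- test_normality(rnorm(25))
    res$p[res$test == "shapiro_wilk"] > 0.05
  }, logical(1L))
  expect_gte(mean(normal_ok), 0.90)

  bimodal_reject <- vapply(1:200, function(i) {
    x <- rnorm(25) + sample(c(-5, 5), 25, replace = TRUE)
    attr(test_normality(x), "non_normal")
  }, logical(1L))
  expect_gte(mean(bimodal_reject), 0.95)

  expect_error(test_normality(rep(2, 25)), "insufficient variation")
  expect_error(test_normality(c(1, 2)), "insufficient data")
})

test_that("Kruskal-Wallis matches the hand rank computation and conventions", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)

  flat <- kruskal_wallis(list(rep(2, 5), rep(2, 5), rep(2, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  expect_error(kruskal_wallis(list(c(1, 2))), "at least 2 groups")
})

test_that("Kruskal-Wallis H equals the enumeration oracle on small inputs", {
  set.seed(53)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    sizes <- pmax(2L, as.integer(rmultinom(1, 10 - 2L * k, rep(1, k))) + 2L)
    values <- if (rep %% 2 == 0) {
      sample(1:5, sum(sizes), replace = TRUE)  # with ties
    } else {
      rnorm(sum(sizes))
    }
    groups <- split(values, rep(seq_len(k), sizes))
    if (length(unique(values)) == 1L) next
    expect_equal(kruskal_wallis(groups)$statistic,
                 oracle_kruskal_H(groups), tolerance = 1e-9)
  }
})

test_that("pairwise Mann-Whitney applies the Bonferroni threshold", {
  groups <- list(A = c(1, 2, 3), B = c(4, 5, 6), C = c(7, 8, 9))
  res <- pairwise_mannwhitney(groups, family_alpha = 0.05, m = 3)
  expect_equal(unique(res$threshold), 0.017)
  expect_equal(nrow(res), 3L)

  ab <- res[res$group1 == "A" & res$group2 == "B", ]
  expect_equal(ab$U, 0)
  expect_equal(ab$p, 0.1, tolerance = 1e-12)
  expect_false(ab$significant)

  same <- pairwise_mannwhitney(list(X = c(1, 2, 3), Y = c(1, 2, 3)), m = 1)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  # threshold is monotone in the comparison count
  thr <- vapply(1:10, function(m) {
    pairwise_mannwhitney(groups, family_alpha = 0.05, m = m)$threshold[1L]
  }, double(1L))
  expect_true(all(diff(thr) <= 0))
})

test_that("Mann-Whitney agrees with exhaustive enumeration on small inputs", {
  set.seed(61)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:(10 - n1 - 1), 1)
    pool <- sample(seq(1, 40, by = 0.5), n1 + n2)  # tie-free
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    res <- pairwise_mannwhitney(list(A = x, B = y), m = 1)
    expect_equal(res$U, oracle_U(x, y))
    expect_true(res$exact)
    expect_equal(res$p, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("precision comparisons detect dispersion, not location", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.8, 3.9)
  shifted <- compare_precision(list(A = x, B = x + 100), m = 1)
  expect_equal(shifted$p, 1)
  expect_false(shifted$significant)

  self <- compare_precision(list(A = x, B = x), m = 1)
  expect_equal(self$p, 1)

  set.seed(71)
  power <- vapply(1:200, function(i) {
    res <- compare_precision(list(A = rnorm(25, 0, 1), B = rnorm(25, 0, 5)),
                             family_alpha = 0.05, m = 3)
    res$significant
  }, logical(1L))
  expect_gte(mean(power), 0.90)
})

test_that("compact letter displays encode exactly the non-significant pairs", {
  mk <- function(sig) {
    data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
               significant = sig)
  }
  none <- assign_letters(mk(c(FALSE, FALSE, FALSE)), c("A", "B", "C"))
  expect_equal(unname(none), c("A", "A", "A"))

  isolated <- assign_letters(mk(c(FALSE, TRUE, TRUE)), c("A", "B", "C"))
  expect_equal(unname(isolated), c("A", "A", "B"))

  all_sig <- assign_letters(mk(c(TRUE, TRUE, TRUE)), c("A", "B", "C"))
  expect_equal(length(unique(all_sig)), 3L)

  lower <- assign_letters(mk(c(FALSE, TRUE, TRUE)), c("A", "B", "C"),
                          case = "lower")
  expect_equal(unname(lower), c("a", "a", "b"))

  expect_error(assign_letters(mk(c(TRUE, TRUE, TRUE))[-1, ], c("A", "B", "C")),
               "incomplete pairwise")
})

test_that("letter sharing is equivalent to non-significance on random patterns", {
  set.seed(83)
  for (rep in 1:50) {
    k <- sample(3:7, 1)
    nm <- paste0("S", seq_len(k))
    pairs <- utils::combn(k, 2L)
    pw <- data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
                     significant = runif(ncol(pairs)) < 0.4)
    lt <- assign_letters(pw, nm)
    share <- function(i, j) {
      a <- strsplit(lt[[i]], ", ")[[1L]]
      b <- strsplit(lt[[j]], ", ")[[1L]]
      length(intersect(a, b)) > 0L
    }
    for (c_idx in seq_len(ncol(pairs))) {
      i <- pairs[1L, c_idx]; j <- pairs[2L, c_idx]
      expect_equal(share(i, j), !pw$significant[c_idx],
                   label = sprintf("rep %d pair %s-%s", rep, nm[i], nm[j]))
    }
  }
})

test_that("the full report assembles summaries, tests and letters", {
  recs <- simulate_strategy_study(n_per_group = 10, seed = 9)
  report <- build_report(recs)
  expect_s3_class(report, "accuracy_report")
  expect_equal(report$threshold, 0.017)
  expect_equal(nrow(report$summaries), 8L * 9L)
  expect_equal(nrow(report$trueness_tests), 8L * choose(9, 2))
  expect_equal(sort(unique(report$letters$parameter)),
               sort(c("deltaL_um", "VE_um", "VE_x_um", "VE_y_um", "VE_z_um",
                      "alpha_overall_deg", "alpha_coronal_deg",
                      "alpha_axial_deg")))
  tables <- report_tables(report)
  expect_equal(nrow(tables$linear), 5L * 9L)
  expect_equal(nrow(tables$angular), 3L * 9L)

  single <- recs[recs$strategy == "FL", ]
  expect_error(build_report(single), "at least 2 strategies")
  expect_error(build_report(recs[, -3]), "missing parameter columns")
})

test_that("null studies give homogeneous letters, inflated variance is isolated", {
  null_profiles <- lapply(paste0("G", 1:3), function(id) {
    strategy_profile(id, t_scale_um = c(80, 80, 80), r_scale_deg = c(0.1, 0.1, 0.1))
  })
  set.seed(97)
  homogeneous <- vapply(1:30, function(r) {
    recs <- simulate_strategy_study(null_profiles, n_per_group = 25,
                                    seed = sample.int(2^31 - 1, 1))
    rpt <- build_report(recs)
    lt <- rpt$letters[rpt$letters$parameter == "VE_x_um", ]
    length(unique(lt$trueness)) == 1L && length(unique(lt$precision)) == 1L
  }, logical(1L))
  expect_gte(mean(homogeneous), 0.90)

  inflated <- c(null_profiles[1:2],
                list(strategy_profile("G3", t_scale_um = c(400, 400, 400),
                                      r_scale_deg = c(0.1, 0.1, 0.1))))
  isolated <- vapply(1:30, function(r) {
    recs <- simulate_strategy_study(inflated, n_per_group = 25,
                                    seed = sample.int(2^31 - 1, 1))
    rpt <- build_report(recs)
    lt <- rpt$letters[rpt$letters$parameter == "VE_x_um", ]
    bad <- lt$precision[lt$strategy == "G3"]
    others <- lt$precision[lt$strategy != "G3"]
    !any(strsplit(bad, ", ")[[1L]] %in% unlist(strsplit(others, ", ")))
  }, logical(1L))
  expect_gte(mean(isolated), 0.80)
})
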