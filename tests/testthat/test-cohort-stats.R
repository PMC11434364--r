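test_that("group assignment follows the boundary conventions", {
  s <- data.frame(
    bmi = c(25, 29.9, 30, 35, 24.9),
    abdominal_circumference = c(81, 93.9, 94, 105, 80),
    visceral_fat = c(16, 16.01, 17.52, 9.5, NA),
    fat_percent = c(35.9, 36, 46, 46.1, 50)
  )
  g <- assign_groups(s)
  expect_equal(as.character(g$bmi_group), c("25-30", "25-30", "30-35", ">=35", NA))
  expect_equal(as.character(g$ac_group), c("81-93", "81-93", "94-104", ">104", NA))
  expect_equal(as.character(g$vf_group), c("<=16", ">16", ">16", "<=16", NA))
  expect_equal(as.character(g$fat_group), c("<36", "36-46", "36-46", ">46", ">46"))
})

test_that("the default cohort splits 23/52 on visceral fat", {
  ch <- simulate_cohort(cohort_design(synthesize_fids = FALSE))
  g <- assign_groups(ch$subjects)
  expect_equal(as.integer(table(g$vf_group)), c(23L, 52L))
})

test_that("Mann-Whitney matches the exact enumeration on small samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1) # 2/20 arrangements at least as extreme
  expect_identical(mw$method, "exact")

  # U_x + U_y = n_x * n_y
  set.seed(1)
  x <- rnorm(8); y <- rnorm(13)
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 8 * 13)

  expect_error(mann_whitney(numeric(0), 1:3), class = "urinmr_validation_error")
})

test_that("Kruskal-Wallis handles ties, degeneracy and reduces to Mann-Whitney", {
  # identical constant groups: H undefined through ties -> 0, 1 by convention
  kw0 <- kruskal_wallis_dunn(list(rep(2, 5), rep(2, 6)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)

  expect_error(kruskal_wallis_dunn(list(1:5)), class = "urinmr_validation_error")
  expect_error(kruskal_wallis_dunn(list(1:5, 3)), class = "urinmr_validation_error")

  # k = 2: H equals the square of the (uncorrected) Mann-Whitney z
  set.seed(4)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  kw <- kruskal_wallis_dunn(list(x, y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-9)

  # large-sample null mean of H is about k - 1
  set.seed(5)
  h <- replicate(300, kruskal_wallis_dunn(
    list(rnorm(30), rnorm(30), rnorm(30)))$H)
  expect_lt(abs(mean(h) - 2), 3 * sd(h) / sqrt(300))
})

test_that("Dunn post-hoc runs only after a significant omnibus and is Bonferroni-monotone", {
  set.seed(6)
  null_groups <- list(rnorm(10), rnorm(10), rnorm(10, 0.05))
  kw_null <- kruskal_wallis_dunn(null_groups)
  if (kw_null$p_value >= 0.05) expect_null(kw_null$posthoc)

  shifted <- list(rnorm(15), rnorm(15, 2), rnorm(15, 4))
  kw <- kruskal_wallis_dunn(shifted)
  expect_lt(kw$p_value, 0.05)
  expect_s3_class(kw$posthoc, "data.frame")
  expect_true(all(kw$posthoc$p_adjusted >= kw$posthoc$p_unadjusted))
  expect_true(all(kw$posthoc$p_adjusted <= 1))
})

test_that("proportion tests select Fisher for sparse 2x2 tables", {
  ft <- compare_proportions(matrix(c(3, 0, 0, 3), 2))
  expect_identical(ft$test, "fisher")
  expect_equal(ft$p_value, 0.1) # hypergeometric point-probability rule

  even <- compare_proportions(matrix(c(10, 10, 10, 10), 2))
  expect_identical(even$test, "chi-square")
  expect_equal(even$p_value, 1)

  big <- matrix(c(20, 30, 25, 25), 2)
  ct <- compare_proportions(big)
  expect_identical(ct$test, "chi-square")
  expect_equal(ct$p_value,
               suppressWarnings(chisq.test(big, correct = FALSE))$p.value)

  expect_error(compare_proportions(matrix(0, 2, 2)),
               class = "urinmr_validation_error")
  expect_error(compare_proportions(matrix(c(1.5, 1, 1, 1), 2)),
               class = "urinmr_validation_error")
})

test_that("Spearman correlation matches the rank formula", {
  expect_equal(spearman_rho(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_equal(spearman_rho(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_rho(1:5, rep(2, 5)), class = "urinmr_validation_error")
  expect_error(spearman_rho(1:2, 1:2), class = "urinmr_validation_error")
})

test_that("ROC analysis is exact on separable data and symmetric under label flips", {
  vals <- c(1, 2, 3, 10, 11, 12)
  labs <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_analysis(vals, labs)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$ppv, 100)
  expect_equal(r$npv, 100)

  set.seed(8)
  v <- rnorm(40)
  l <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_analysis(v, !l)$auc, 1 - roc_analysis(v, l)$auc,
               tolerance = 1e-12)
  expect_error(roc_analysis(v, rep(TRUE, 40)), class = "urinmr_validation_error")

  # the curve is monotone nondecreasing in both coordinates
  cur <- roc_analysis(v, l)$curve
  expect_true(all(diff(cur$fpr) >= 0))
  expect_true(all(diff(cur$tpr) >= 0))
})

test_that("trapezoidal AUC equals the Mann-Whitney U identity, ties included", {
  set.seed(9)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    v <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n0), 1)) # ties likely
    l <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_analysis(v, l)
    u <- mann_whitney(v[l], v[!l])$U
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  v <- rnorm(60)
  l <- rbinom(60, 1, plogis(v)) == 1
  r <- roc_analysis(v, l)
  pr <- suppressMessages(pROC::roc(l, v, direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- suppressMessages(as.numeric(pROC::ci.auc(pr, method = "delong")))
  expect_equal(r$auc_ci, ci[c(1, 3)], tolerance = 1e-8)
  # the chosen cutoff attains the maximal Youden index
  co <- suppressMessages(pROC::coords(pr, "best", best.method = "youden",
                                      transpose = FALSE))
  expect_equal((r$sensitivity + r$specificity) / 100 - 1,
               max(co$sensitivity + co$specificity) - 1, tolerance = 1e-12)
})

test_that("predictive values reconstruct the implied confusion table", {
  sar <- ppv_npv_from_accuracy(65, 69, 52L, 23L)
  expect_equal(sar$ppv, 83)
  expect_equal(sar$npv, 47)
  expect_equal(ppv_npv_from_accuracy(100, 100, 52L, 23L)$ppv, 100)
  expect_equal(ppv_npv_from_accuracy(0, 100, 5L, 5L)$ppv_defined, FALSE)
  expect_error(ppv_npv_from_accuracy(120, 50, 5L, 5L),
               class = "urinmr_validation_error")

  # Bayes consistency with direct counting when the implied counts are
  # integers
  vals <- c(11:18, 5.5, 5.6, 1:6, 15.5, 16.5) # 10 positives, 8 negatives
  labs <- rep(c(TRUE, FALSE), c(10, 8))
  r <- roc_analysis(vals, labs)
  pp <- ppv_npv_from_accuracy(r$sensitivity, r$specificity, 10L, 8L)
  expect_equal(pp$ppv, round(r$ppv))
  expect_equal(pp$npv, round(r$npv))
})

test_that("rank-based tests are invariant under monotone transforms", {
  set.seed(11)
  x <- rlnorm(20); y <- rlnorm(25, 0.4)
  expect_equal(mann_whitney(x, y)$p_value,
               mann_whitney(log(x), log(y))$p_value, tolerance = 1e-12)
  g <- list(rlnorm(10), rlnorm(10, 0.3), rlnorm(10, 0.6))
  expect_equal(kruskal_wallis_dunn(g)$p_value,
               kruskal_wallis_dunn(lapply(g, sqrt))$p_value, tolerance = 1e-12)
  l <- rep(c(TRUE, FALSE), c(20, 25))
  expect_equal(roc_analysis(c(x, y), l)$auc,
               roc_analysis(log(c(x, y)), l)$auc, tolerance = 1e-12)
})

test_that("group tables cover all four schemes and detect the injected effects", {
  d <- reduced_design(seed = 314L)
  ch <- simulate_cohort(d)
  spectra <- lapply(ch$fids, process_fid)
  conc <- quantify_panel(spectra, default_lib, quant_config())
  labeled <- assign_groups(ch$subjects)
  tabs <- run_group_tables(conc, labeled)

  expect_named(tabs, c("bmi", "ac", "vf", "fat"))
  for (tab in tabs) {
    expect_identical(tab$metabolite, conc$metabolites)
    expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  }
  expect_identical(unique(tabs$vf$test), "Mann-Whitney")
  expect_true(all(tabs$bmi$test == "Kruskal-Wallis"))

  markers <- c("Sarcosine", "Trigonelline", "Phenylalanine")
  expect_true(all(tabs$vf$p_value[tabs$vf$metabolite %in% markers] < 0.05))

  # monotone transform of concentrations leaves the rank tests unchanged
  conc2 <- conc
  conc2$matrix <- exp(conc$matrix / max(abs(conc$matrix)))
  tabs2 <- run_group_tables(conc2, labeled)
  expect_equal(tabs2$vf$p_value, tabs$vf$p_value, tolerance = 1e-12)

  # id misalignment is reported with the offenders
  bad <- labeled
  bad$id[1] <- "SOMEONE_ELSE"
  expect_error(run_group_tables(conc, bad), "SOMEONE_ELSE",
               class = "urinmr_alignment_error")
})
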