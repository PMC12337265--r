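test_that("ROI means average defined in-mask voxels only", {
  m <- array(c(1, NaN, 3, 100), c(2, 2, 1))
  msk <- array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1))
  expect_equal(extract_roi_mean(m, msk), 2)       # NaN excluded from the mean
  expect_error(extract_roi_mean(m, array(TRUE, c(2, 1, 1))), "shape")
  msk2 <- array(c(FALSE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_error(extract_roi_mean(m, msk2), "no defined voxels")
  bm <- biometric_map(array(1:8, c(2, 2, 2)), kind = "CV",
                      band = frequency_band(0.95, 1.05, "cardiac"))
  expect_equal(extract_roi_mean(bm, array(TRUE, c(2, 2, 2))), 4.5)
})

test_that("ROC AUC follows the Mann-Whitney pair count", {
  expect_equal(roc_auc(c(1, 2), c(1.5, 3)), 0.75)
  expect_equal(roc_auc(1:5, 6:10), 1)             # perfect separation
  expect_equal(roc_auc(6:10, 1:5), 0)
  expect_equal(roc_auc(c(1, 1), c(1, 1)), 0.5)    # ties split evenly
  set.seed(22)
  a <- rnorm(13); b <- rnorm(21, 0.5)
  expect_equal(roc_auc(a, b) + roc_auc(b, a), 1)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(a), exp(b)), roc_auc(a, b))
  expect_equal(roc_auc(a^3, b^3), roc_auc(a, b))
  # agreement with the Wilcoxon rank-sum statistic
  w <- wilcox.test(b, a, exact = FALSE)$statistic
  expect_equal(roc_auc(a, b), unname(w) / (13 * 21))
  expect_error(roc_auc(numeric(0), 1:3), "nonempty")
})

test_that("the omnibus gate routes by per-group Shapiro-Wilk normality", {
  set.seed(23)
  norm3 <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  g1 <- omnibus_gate(norm3)
  expect_equal(g1$plan, "parametric")
  expect_length(g1$shapiro_p, 3)

  skewed <- norm3
  skewed$b <- rexp(30)^3                      # heavy skew rejects normality
  expect_equal(omnibus_gate(skewed)$plan, "nonparametric")

  expect_warning(gc <- omnibus_gate(list(a = rnorm(10), b = rep(2, 10))),
                 "constant")
  expect_equal(gc$plan, "nonparametric")
  expect_true(is.na(gc$shapiro_p["b"]))
  expect_error(omnibus_gate(list(a = 1:2, b = 1:5)), ">= 3")
})

test_that("Kruskal-Wallis + Dunn/Holm matches the hand-computed oracle", {
  s <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  got <- kruskal_dunn_holm(s)
  # ranks 1..9: mean ranks 2, 5, 8; H = 12/90 * (3*9 + 0 + 3*9) = 7.2
  expect_equal(got$H, 7.2, tolerance = 1e-12)
  expect_equal(got$omnibus_p, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  z13 <- -6 / sqrt((9 * 10 / 12) * (2 / 3))   # = -2.68328
  z12 <- -3 / sqrt((9 * 10 / 12) * (2 / 3))
  pw <- got$pairwise
  key <- paste(pw$group1, pw$group2)
  expect_equal(pw$z[key == "g1 g3"], z13, tolerance = 1e-10)
  expect_equal(pw$z[key == "g1 g2"], z12, tolerance = 1e-10)
  expect_equal(pw$z[key == "g2 g3"], z12, tolerance = 1e-10)
  # Holm by hand: sorted raw p (p13 < p12 = p23)
  p13 <- 2 * pnorm(z13); p12 <- 2 * pnorm(z12)
  expect_equal(pw$p_adj[key == "g1 g3"], 3 * p13, tolerance = 1e-10)
  expect_equal(pw$p_adj[key == "g1 g2"], 2 * p12, tolerance = 1e-10)
  expect_equal(pw$p_adj[key == "g2 g3"], 2 * p12, tolerance = 1e-10)

  # tie correction: duplicated values shrink the variance term
  st <- list(a = c(1, 1, 2), b = c(2, 3, 3))
  kw <- kruskal.test(list(st$a, st$b))
  expect_equal(kruskal_dunn_holm(st)$H, unname(kw$statistic),
               tolerance = 1e-12)
  expect_error(kruskal_dunn_holm(list(a = 1:3)), ">= 2 groups")
})

test_that("ANOVA + Tukey agrees with F = t^2 for two groups and finds real shifts", {
  set.seed(24)
  a <- rnorm(15); b <- rnorm(15, 0.3)
  got <- anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(got$omnibus_p, tt$p.value, tolerance = 1e-8)

  big <- list(a = rnorm(40), b = rnorm(40, 2), c = rnorm(40, 4))
  g3 <- anova_tukey(big)
  expect_lt(g3$omnibus_p, 1e-6)
  expect_true(all(g3$pairwise$p_adj < 0.01))
  expect_equal(nrow(g3$pairwise), 3)
  expect_error(anova_tukey(list(a = rep(1, 3), b = rep(2, 3))), "undefined")
  expect_error(anova_tukey(list(a = 1:3)), ">= 2 groups")
})

test_that("the mutual-ROI pipeline separates ordered groups end to end", {
  set.seed(25)
  d <- c(4, 4, 2)
  shift <- c(NT1 = 0, awake = 0.6, sleep = 1.2)
  design <- data.frame(
    subject_id = sprintf("s%02d", 1:24),
    group = rep(names(shift), each = 8),
    age = round(rnorm(24, 40, 8)), sex = rep(0:1, 12),
    stringsAsFactors = FALSE)
  maps <- lapply(seq_len(24), function(i) {
    g <- design$group[i]
    array(rnorm(prod(d), 0, 0.3) + shift[[g]], d)
  })
  # pairwise masks: pretend each comparison flagged an overlapping slab
  m1 <- array(FALSE, d); m1[1:3, , ] <- TRUE
  m2 <- array(FALSE, d); m2[2:4, , ] <- TRUE
  res <- mutual_roi_analysis(maps, design, list(m1, m2),
                             auc_pairs = list(c("NT1", "awake"),
                                              c("NT1", "sleep"),
                                              c("awake", "sleep")))
  expect_equal(sum(res$mask), sum(m1 & m2))
  expect_equal(nrow(res$roi_samples), 24)
  expect_true(all(res$auc$auc > 0.8))
  expect_gt(res$auc$auc[res$auc$higher == "sleep" &
                          res$auc$lower == "NT1"], 0.95)
  expect_lt(res$tests$omnibus_p, 0.01)
  expect_true(res$plan %in% c("parametric", "nonparametric"))
  expect_error(mutual_roi_analysis(maps, design, list(m1 & FALSE)),
               "empty")
})
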