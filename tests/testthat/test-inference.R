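make_design <- function(groups, age = NULL, sex = NULL) {
  n <- length(groups)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = groups,
             age = if (is.null(age)) seq(30, 50, length.out = n) else age,
             sex = if (is.null(sex)) rep(0:1, length.out = n) else sex,
             stringsAsFactors = FALSE)
}

rand_maps <- function(n, d = c(3, 3, 3), seed = 1, shift = rep(0, n)) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    array(rnorm(prod(d)) + shift[i], c(d, 1)[1:3]))
}

test_that("the GLM contrast reduces to the pooled two-sample t statistic", {
  set.seed(11)
  d <- c(3, 3, 2)
  maps <- lapply(1:10, function(i) array(rnorm(prod(d), mean = i > 5), d))
  des <- make_design(rep(c("A", "B"), each = 5))
  fit <- fit_glm_contrast(maps, des, c(B = 1, A = -1),
                          covariates = character(0))
  v <- 7   # arbitrary voxel
  a <- vapply(maps[1:5], function(m) m[v], 0)
  b <- vapply(maps[6:10], function(m) m[v], 0)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(fit$t[v], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fit$df, 8)
})

test_that("orthogonal covariates leave the contrast t unchanged", {
  set.seed(12)
  d <- c(3, 3, 2)
  maps <- lapply(1:12, function(i) array(rnorm(prod(d)), d))
  # covariates balanced across groups and mutually orthogonal after centering
  age <- rep(c(-1, 0, 1, -1, 0, 1), 2) + 40
  sex <- rep(c(0, 1), 6)
  des <- make_design(rep(c("A", "B"), each = 6), age = age, sex = sex)
  f0 <- fit_glm_contrast(maps, des, c(A = 1, B = -1),
                         covariates = character(0))
  f1 <- fit_glm_contrast(maps, des, c(A = 1, B = -1))
  expect_equal(sign(f1$t), sign(f0$t))
  expect_gt(cor(as.vector(f0$t), as.vector(f1$t)), 0.98)
  # oracle: stats::lm with treatment coding gives the same adjusted t
  for (v in c(1, 9, 18)) {
    y <- vapply(maps, function(m) m[v], 0)
    fit <- lm(y ~ group + age + sex, data = des)
    expect_equal(f1$t[v],
                 -summary(fit)$coefficients["groupB", "t value"],
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are rejected with the offending column named", {
  maps <- rand_maps(6, c(2, 2, 2), seed = 3)
  des <- make_design(rep(c("A", "B"), 3))
  des$dup <- des$age          # exact copy -> collinear
  expect_error(fit_glm_contrast(maps, des, c(A = 1, B = -1),
                                covariates = c("age", "dup")),
               "collinear")
  # constant covariate centers to zero -> rank deficient too
  des$flat <- 1
  expect_error(fit_glm_contrast(maps, des, c(A = 1, B = -1),
                                covariates = "flat"), "rank-deficient")
  expect_error(fit_glm_contrast(maps, des, c(1, -1),
                                covariates = character(0)), "named")
  expect_error(fit_glm_contrast(maps, des, c(A = 1, C = -1),
                                covariates = character(0)), "not in design")
})

test_that("TFCE matches its closed form and the brute-force oracle", {
  # single voxel, height 1: sum over 100 steps of 1^0.5 * h^2 * dh -> ~1/3
  a <- array(0, c(3, 3, 3)); a[2, 2, 2] <- 1
  ours <- tfce(a)
  expect_equal(ours[2, 2, 2], sum(((1:100) / 100)^2) / 100, tolerance = 1e-12)
  expect_equal(ours[2, 2, 2], 1 / 3, tolerance = 0.02)
  expect_equal(sum(ours != 0), 1)

  # random maps vs the igraph component-labelling oracle, both connectivities
  set.seed(14)
  for (i in 1:6) {
    conn <- if (i %% 2) 26 else 6
    s <- array(rnorm(6^3), c(6, 6, 6))
    expect_equal(tfce(s, connectivity = conn),
                 tfce_oracle(pmax(s, 0), connectivity = conn),
                 tolerance = 1e-10)
  }

  # all-negative map enhances to zero; determinism
  expect_true(all(tfce(array(-abs(rnorm(27)), c(3, 3, 3))) == 0))
  s2 <- array(rnorm(5^3), c(5, 5, 5))
  expect_identical(tfce(s2), tfce(s2))

  # masked voxels contribute nothing and split clusters
  b <- array(1, c(3, 1, 1))
  m <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
  tb <- tfce(b, mask = m, connectivity = 6)
  expect_equal(tb[2, 1, 1], 0)
  expect_equal(tb[1, 1, 1], tb[3, 1, 1])
  expect_lt(tb[1, 1, 1], tfce(b, connectivity = 6)[1, 1, 1])
  expect_error(tfce(a, connectivity = 18), "6 or 26")
})

test_that("permutation inference is seeded, label-symmetric and monotone", {
  set.seed(15)
  d <- c(4, 4, 2)
  shift <- c(rep(0, 6), rep(1.2, 6))
  maps <- lapply(1:12, function(i) array(rnorm(prod(d)) + shift[i] *
                                           (arrayInd(1:prod(d), d)[, 1] <= 2), d))
  des <- make_design(rep(c("A", "B"), each = 6))

  r1 <- permutation_fwe(maps, des, c(B = 1, A = -1), n_perm = 60,
                        seed = 7, allow_small = TRUE)
  r2 <- permutation_fwe(maps, des, c(B = 1, A = -1), n_perm = 60,
                        seed = 7, allow_small = TRUE)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p >= 1 / 61 - 1e-12 & r1$p <= 1, na.rm = TRUE))

  # swapping group labels while negating the contrast is a no-op
  des_sw <- des; des_sw$group <- ifelse(des$group == "A", "B", "A")
  r3 <- permutation_fwe(maps, des_sw, c(A = 1, B = -1), n_perm = 60,
                        seed = 7, allow_small = TRUE)
  expect_equal(r3$p, r1$p, tolerance = 1e-12)
  expect_equal(r3$t, r1$t, tolerance = 1e-12)

  # without TFCE, corrected p is monotone nonincreasing in the t statistic
  r4 <- permutation_fwe(maps, des, c(B = 1, A = -1), n_perm = 60,
                        seed = 3, use_tfce = FALSE, allow_small = TRUE)
  ord <- order(r4$t)
  expect_true(all(diff(r4$p[ord]) <= 1e-12))

  expect_error(permutation_fwe(maps, des, c(B = 1, A = -1), n_perm = 50),
               "allow_small")
})

test_that("significant masks report voxel counts and cm^3 volumes", {
  tm <- array(rnorm(64), c(4, 4, 4))
  pm <- array(1, c(4, 4, 4))
  pm[1:28] <- 0.01
  sm <- stat_map(tm, pm, contrast = "B - A", n_perm = 250, seed = 1)
  got <- significant_mask(sm, alpha = 0.05)
  expect_equal(got$n_voxels, 28)
  expect_equal(got$volume_cm3, 0.8)        # 28 * 27 / 1000, one decimal
  expect_true(all(which(got$mask) == 1:28))

  none <- significant_mask(stat_map(tm, array(1, c(4, 4, 4)),
                                    contrast = "x", n_perm = 250, seed = 1))
  expect_equal(none$n_voxels, 0)
  expect_equal(significant_mask(sm, alpha = 0)$n_voxels, 0)
})

test_that("the mutual mask is an exact voxel-wise AND", {
  set.seed(16)
  ms <- lapply(1:3, function(i) array(runif(27) > 0.4, c(3, 3, 3)))
  got <- mutual_mask(ms)
  want <- ms[[1]] & ms[[2]] & ms[[3]]
  expect_identical(got, want)
  expect_identical(mutual_mask(ms[1]), ms[[1]])
  expect_error(mutual_mask(list(ms[[1]], array(TRUE, c(2, 2, 2)))),
               "differ")
  expect_error(mutual_mask(list()), "at least one")
})
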