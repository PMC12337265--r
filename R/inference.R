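# stack per-subject maps into an n x V matrix
.map_matrix <- function(maps) {
  arrs <- lapply(maps, function(m)
    if (inherits(m, "biometric_map")) m$values else m)
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d)) stop("map shapes differ")
  list(Y = do.call(rbind, lapply(arrs, as.vector)), dims = d)
}

# group + covariate design matrices; errors on rank deficiency
.build_design <- function(design, covariates = c("age", "sex")) {
  design <- validate_design(design)
  G <- stats::model.matrix(~ 0 + group, data = design)
  colnames(G) <- levels(design$group)
  Z <- NULL
  if (length(covariates)) {
    Z <- as.matrix(design[, covariates, drop = FALSE])
    Z <- scale(Z, center = TRUE, scale = FALSE)   # centered nuisance
  }
  X <- cbind(G, Z)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  list(X = X, groups = levels(design$group), n_groups = ncol(G))
}

# contrast spec (named over groups) -> full-length contrast vector
.contrast_vector <- function(contrast, dm) {
  cvec <- numeric(ncol(dm$X))
  names(cvec) <- colnames(dm$X)
  if (is.null(names(contrast)))
    stop("contrast must be a named vector over group levels, e.g. c(A = 1, B = -1)")
  unknown <- setdiff(names(contrast), dm$groups)
  if (length(unknown))
    stop("contrast names not in design groups: ",
         paste(unknown, collapse = ", "))
  cvec[names(contrast)] <- contrast
  cvec
}

# vectorized OLS t statistics for one contrast: Y is n x V
.ols_t <- function(Y, X, cvec) {
  XtXi <- solve(crossprod(X))
  pinv <- XtXi %*% t(X)
  B <- pinv %*% Y
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(cvec) %*% XtXi %*% cvec)
  drop(cvec %*% B) / sqrt(sigma2 * cvar)
}

#' Voxel-wise GLM contrast t map
#'
#' Ordinary-least-squares fit per voxel with intercept-per-group coding
#' plus centered nuisance covariates (default age and sex), returning the
#' t statistic of a group-difference contrast. With two groups and no
#' covariates this reduces exactly to the pooled-variance two-sample t
#' statistic.
#'
#' @param maps list of per-subject [biometric_map]s (or 3D arrays), in
#'   design row order.
#' @param design cohort design data.frame (`subject_id`, `group`, `age`,
#'   `sex`).
#' @param contrast named numeric over group levels, e.g.
#'   `c(sleep = 1, awake = -1)`.
#' @param covariates design columns used as nuisance regressors
#'   (`character(0)` for none).
#' @param mask optional 3D analysis mask; voxels with missing values in any
#'   subject are dropped from the mask.
#' @return list with `t` (3D array, `NA` outside the analysis mask),
#'   `mask`, `df`.
#' @export
fit_glm_contrast <- function(maps, design, contrast,
                             covariates = c("age", "sex"), mask = NULL) {
  mm <- .map_matrix(maps)
  if (nrow(mm$Y) != nrow(design))
    stop("number of maps (", nrow(mm$Y), ") != design rows (",
         nrow(design), ")")
  dm <- .build_design(design, covariates)
  cvec <- .contrast_vector(contrast, dm)
  amask <- colSums(!is.finite(mm$Y)) == 0
  if (!is.null(mask)) amask <- amask & as.vector(mask != 0)
  tvals <- rep(NA_real_, ncol(mm$Y))
  tvals[amask] <- .ols_t(mm$Y[, amask, drop = FALSE], dm$X, cvec)
  list(t = array(tvals, mm$dims), mask = array(amask, mm$dims),
       df = nrow(dm$X) - ncol(dm$X))
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_{h = dh, 2dh, ... <= s_v} extent(cluster of v at h)^E *
#' h^H * dh` with 26- (default) or 6-neighbourhood clusters. Only positive
#' statistic values are enhanced; pass `-stat` for the negative tail.
#'
#' @param stat3d 3D statistic array.
#' @param mask 3D logical mask; default = finite voxels.
#' @param H height exponent.
#' @param E extent exponent.
#' @param dh integration step; `NULL` uses `max(stat)/n_steps`.
#' @param n_steps number of integration steps when `dh` is `NULL`.
#' @param connectivity 6 or 26.
#' @return 3D array of enhanced values (0 outside the mask).
#' @export
tfce <- function(stat3d, mask = NULL, H = 2, E = 0.5, dh = NULL,
                 n_steps = 100, connectivity = 26) {
  stopifnot(is.array(stat3d), length(dim(stat3d)) == 3L, H > 0, E > 0)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (is.null(mask)) mask <- is.finite(stat3d)
  if (!identical(dim(mask), dim(stat3d))) stop("mask shape mismatch")
  mask <- mask != 0 & is.finite(stat3d)
  if (!any(mask)) stop("empty mask")
  s <- stat3d
  s[!mask] <- 0
  mx <- max(s[mask], 0)
  if (is.null(dh)) dh <- mx / n_steps
  if (mx <= 0 || dh <= 0) return(array(0, dim(stat3d)))
  out <- tfce_cpp(as.numeric(s), as.integer(dim(stat3d)),
                  as.logical(mask), H, E, dh, as.integer(connectivity))
  array(out, dim(stat3d))
}

#' Permutation FWE-corrected group inference
#'
#' One-sided max-statistic permutation test of a group contrast with
#' Freedman--Lane nuisance handling: the maps are residualized on the
#' nuisance model (intercept + covariates), residual rows are permuted
#' with a seeded generator, the full model is refit, the t map is
#' (optionally) TFCE-enhanced, and the maximum enhanced statistic per
#' permutation forms the null distribution. Corrected
#' `p_v = (1 + #\{perm max >= observed_v\}) / (1 + n_perm)`.
#'
#' @inheritParams fit_glm_contrast
#' @param n_perm number of permutations (>= 100 for inference; smaller
#'   values need `allow_small = TRUE`).
#' @param seed RNG seed (same seed + inputs gives bit-identical p maps).
#' @param alpha significance level recorded in the result.
#' @param use_tfce enhance with [tfce()]?
#' @param tfce_params list of [tfce()] parameters.
#' @param allow_small permit `n_perm < 100` (testing only).
#' @return a [stat_map] with the observed `t`, corrected `p` (NA outside
#'   the analysis mask) and metadata.
#' @export
permutation_fwe <- function(maps, design, contrast,
                            covariates = c("age", "sex"), mask = NULL,
                            n_perm = 250, seed = NULL, alpha = 0.05,
                            use_tfce = TRUE,
                            tfce_params = list(H = 2, E = 0.5,
                                               n_steps = 100,
                                               connectivity = 26),
                            allow_small = FALSE) {
  if (n_perm < 100 && !allow_small)
    stop("n_perm < 100 is unusable for inference; ",
         "set allow_small = TRUE for smoke tests only")
  mm <- .map_matrix(maps)
  if (nrow(mm$Y) != nrow(design))
    stop("number of maps != design rows")
  dm <- .build_design(design, covariates)
  cvec <- .contrast_vector(contrast, dm)
  amask <- colSums(!is.finite(mm$Y)) == 0
  if (!is.null(mask)) amask <- amask & as.vector(mask != 0)
  if (!any(amask)) stop("empty analysis mask")
  Y <- mm$Y[, amask, drop = FALSE]
  n <- nrow(Y)
  mask3 <- array(amask, mm$dims)

  enhance <- function(tv) {
    tm <- array(0, mm$dims)
    tm[amask] <- tv
    if (use_tfce)
      do.call(tfce, c(list(stat3d = tm, mask = mask3), tfce_params))[amask]
    else pmax(tv, 0)
  }

  t_obs <- .ols_t(Y, dm$X, cvec)
  e_obs <- enhance(t_obs)

  # Freedman-Lane: residualize on the nuisance-only model
  Z <- cbind(`(Intercept)` = 1, dm$X[, -(seq_len(dm$n_groups)),
                                     drop = FALSE])
  Zfit <- Z %*% (solve(crossprod(Z)) %*% crossprod(Z, Y))
  Eres <- Y - Zfit

  count <- numeric(ncol(Y))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pr <- sample.int(n)
      Ystar <- Zfit + Eres[pr, , drop = FALSE]
      mx <- max(enhance(.ols_t(Ystar, dm$X, cvec)))
      count <- count + (mx >= e_obs)
    }
  })
  pcorr <- (1 + count) / (1 + n_perm)

  tmap <- array(NA_real_, mm$dims); tmap[amask] <- t_obs
  pmap <- array(NA_real_, mm$dims); pmap[amask] <- pcorr
  stat_map(tmap, pmap,
           contrast = paste(names(contrast), contrast, sep = "*",
                            collapse = " + "),
           n_perm = n_perm, seed = if (is.null(seed)) NA_integer_ else seed,
           mask = mask3)
}

#' Significant-voxel mask from a statistic map
#'
#' @param statmap a [stat_map].
#' @param alpha significance level; voxels with corrected `p < alpha`.
#' @return list with `mask` (3D logical), `n_voxels` and `volume_cm3`
#'   (reported via [voxels_to_volume_cm3()]).
#' @export
significant_mask <- function(statmap, alpha = 0.05) {
  stopifnot(inherits(statmap, "stat_map"))
  m <- !is.na(statmap$p) & statmap$p < alpha
  list(mask = m, n_voxels = sum(m),
       volume_cm3 = voxels_to_volume_cm3(sum(m), statmap$voxel_size_mm))
}

#' Mutual difference mask
#'
#' Voxel-wise logical AND of binary masks: the region where a difference
#' is present in every comparison.
#'
#' @param masks list of 3D logical/0-1 arrays of identical shape.
#' @return 3D logical array.
#' @export
mutual_mask <- function(masks) {
  if (!length(masks)) stop("need at least one mask")
  d <- dim(masks[[1]])
  out <- array(TRUE, d)
  for (m in masks) {
    if (!identical(dim(m), d)) stop("mask shapes differ")
    out <- out & (m != 0)
  }
  out
}
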