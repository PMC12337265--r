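#' Mean biometric value in an ROI
#'
#' Arithmetic mean over in-mask, defined (non-`NaN`) voxels.
#'
#' @param map a [biometric_map] or 3D array.
#' @param mask 3D logical/0-1 array.
#' @return scalar mean.
#' @export
extract_roi_mean <- function(map, mask) {
  values <- if (inherits(map, "biometric_map")) map$values else map
  if (!identical(dim(values), dim(mask))) stop("mask shape mismatch")
  sel <- values[mask != 0]
  sel <- sel[is.finite(sel)]
  if (!length(sel)) stop("no defined voxels inside the ROI")
  mean(sel)
}

#' ROC area under the curve (Mann--Whitney form)
#'
#' `AUC = (#\{a < b\} + 0.5 * #\{a = b\}) / (n_a * n_b)` over all pairs,
#' with `b` the hypothesized-higher group: the probability that a value
#' from `values_b` exceeds one from `values_a`. Satisfies
#' `roc_auc(a, b) + roc_auc(b, a) = 1` and is invariant under strictly
#' monotone transforms.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be nonempty")
  cmp <- outer(values_a, values_b, "<")
  ties <- outer(values_a, values_b, "==")
  (sum(cmp) + 0.5 * sum(ties)) / (length(values_a) * length(values_b))
}

#' Normality-gated omnibus test plan
#'
#' Shapiro--Wilk per group: if any group rejects normality at `alpha`, the
#' nonparametric plan (Kruskal--Wallis + Dunn/Holm) is chosen, else the
#' parametric plan (one-way ANOVA + Tukey HSD). A constant (zero-variance)
#' group cannot be tested and falls to the nonparametric plan with a
#' warning.
#'
#' @param samples named list of numeric vectors (>= 3 values each).
#' @param alpha Shapiro--Wilk significance level.
#' @return list with `plan` (`"nonparametric"` or `"parametric"`) and
#'   `shapiro_p` (per group, `NA` for constant groups).
#' @export
omnibus_gate <- function(samples, alpha = 0.05) {
  if (any(vapply(samples, length, 0L) < 3))
    stop("need >= 3 values per group")
  sw <- vapply(samples, function(x) {
    if (stats::var(x) == 0) NA_real_ else shapiro.test(x)$p.value
  }, 0)
  if (anyNA(sw)) {
    warning("constant group: Shapiro-Wilk undefined, using nonparametric plan")
    return(list(plan = "nonparametric", shapiro_p = sw))
  }
  list(plan = if (any(sw < alpha)) "nonparametric" else "parametric",
       shapiro_p = sw)
}

# samples list -> long (value, group) frame
.long_samples <- function(samples) {
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  data.frame(value = unlist(samples, use.names = FALSE),
             group = factor(rep(names(samples),
                                vapply(samples, length, 0L))))
}

#' Kruskal--Wallis omnibus with Dunn/Holm post hoc
#'
#' Kruskal--Wallis H (tie-corrected, via [stats::kruskal.test()]) followed
#' by pairwise Dunn z tests on the pooled mid-ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p values
#' and Holm--Bonferroni step-down adjustment.
#'
#' @param samples named list of numeric vectors (>= 2 groups).
#' @return list with `omnibus_p`, `H`, and `pairwise` (data.frame:
#'   group1, group2, z, p, p_adj).
#' @export
kruskal_dunn_holm <- function(samples) {
  if (length(samples) < 2) stop("need >= 2 groups")
  df <- .long_samples(samples)
  kw <- kruskal.test(value ~ group, data = df)
  N <- nrow(df)
  r <- rank(df$value)
  rbar <- tapply(r, df$group, mean)
  n <- tapply(r, df$group, length)
  tie_tab <- table(df$value)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  gnames <- levels(df$group)
  pairs <- utils::combn(gnames, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = as.numeric(z), p = as.numeric(p),
                   p_adj = p.adjust(p, "holm"),
                   stringsAsFactors = FALSE)
  list(omnibus_p = kw$p.value, H = unname(kw$statistic), pairwise = pw)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param samples named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return list with `omnibus_p`, `F`, and `pairwise` (data.frame:
#'   group1, group2, diff, p_adj).
#' @export
anova_tukey <- function(samples) {
  if (length(samples) < 2) stop("need >= 2 groups")
  if (any(vapply(samples, length, 0L) < 2))
    stop("need >= 2 values per group")
  if (all(vapply(samples, stats::var, 0) == 0))
    stop("zero within-group variance everywhere: ANOVA undefined")
  df <- .long_samples(samples)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  list(omnibus_p = an[["Pr(>F)"]][1], F = an[["F value"]][1],
       pairwise = data.frame(
         group1 = vapply(prs, `[`, "", 1),
         group2 = vapply(prs, `[`, "", 2),
         diff = tk[, "diff"], p_adj = tk[, "p adj"],
         stringsAsFactors = FALSE, row.names = NULL))
}

#' Mutual-ROI group separation analysis
#'
#' The end-to-end ROI stage: intersect the pairwise significant masks into
#' the mutual difference mask, extract each subject's mean biometric inside
#' it, compute pairwise ROC AUCs (second-listed group hypothesized higher)
#' and run the normality-gated omnibus + post-hoc scheme.
#'
#' @param maps list of per-subject [biometric_map]s in design order.
#' @param design cohort design data.frame.
#' @param masks list of binary difference masks (one per pairwise
#'   comparison) to intersect.
#' @param auc_pairs list of `c(lower, higher)` group-name pairs for AUC;
#'   default every pair in group-level order.
#' @return list with `mask`, `roi_samples` (subject_id, group, value),
#'   `auc` (data.frame), `plan` and `tests` (omnibus + post-hoc output).
#' @export
mutual_roi_analysis <- function(maps, design, masks, auc_pairs = NULL) {
  design <- validate_design(design)
  roi <- mutual_mask(masks)
  if (!sum(roi)) stop("mutual mask is empty")
  vals <- vapply(maps, extract_roi_mean, 0, mask = roi)
  samples <- split(vals, design$group)
  roi_samples <- data.frame(subject_id = design$subject_id,
                            group = design$group, value = vals,
                            stringsAsFactors = FALSE)
  if (is.null(auc_pairs)) {
    prs <- utils::combn(levels(design$group), 2)
    auc_pairs <- lapply(seq_len(ncol(prs)), function(i) prs[, i])
  }
  auc <- do.call(rbind, lapply(auc_pairs, function(pr)
    data.frame(lower = pr[1], higher = pr[2],
               auc = roc_auc(samples[[pr[1]]], samples[[pr[2]]]),
               stringsAsFactors = FALSE)))
  gate <- omnibus_gate(samples)
  tests <- if (gate$plan == "nonparametric") kruskal_dunn_holm(samples)
           else anova_tukey(samples)
  list(mask = roi, roi_samples = roi_samples, auc = auc,
       plan = gate$plan, tests = tests)
}
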