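## Cohort statistics: group descriptives, t / chi-square tests, ANCOVA
## adjusting for age, sex, and axial length, and table-shaped reports.
##
## Both eyes enter as independent rows (the unit-of-analysis choice of the
## emulated study); `subject_mean = TRUE` collapses to per-subject means
## for sensitivity analysis.

#' Group descriptives (mean ± SD)
#'
#' @param table Data frame with a `group` column.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping column.
#' @return Data frame with group, n, mean, sd (sample SD, n-1 denominator;
#'   `NA` with a warning for singleton groups).
#' @export
describe_by_group <- function(table, outcome, group = "group") {
  g <- factor(table[[group]])
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    x <- table[[outcome]][g == lv]
    x <- x[!is.na(x)]
    if (length(x) < 2) warnf("group %s: sd undefined (n = %d)", lv, length(x))
    data.frame(group = lv, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-group independent-samples t-test
#'
#' Pooled-variance by default (Welch via `var_equal = FALSE`), two-sided.
#' @param table Data frame with a two-level `group` column.
#' @param outcome Outcome column name.
#' @param group Grouping column name.
#' @param var_equal Pooled-variance assumption.
#' @return Named vector `t`, `df`, `p`, `diff` (first level minus second).
#' @export
group_t_test <- function(table, outcome, group = "group", var_equal = TRUE) {
  g <- factor(table[[group]])
  if (nlevels(g) != 2) stopf("t test: need exactly two groups")
  x <- table[[outcome]][g == levels(g)[1]]
  y <- table[[outcome]][g == levels(g)[2]]
  if (var_equal && stats::var(x) + stats::var(y) == 0) {
    stopf("t test: zero pooled variance")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, diff = mean(x) - mean(y))
}

#' Chi-square test of a categorical variable against group
#'
#' Pearson chi-square without continuity correction by default.
#' @param table Data frame.
#' @param categorical Categorical column name.
#' @param group Grouping column name.
#' @param correct Apply Yates continuity correction.
#' @return Named vector `chisq`, `df`, `p`.
#' @export
group_chi_square <- function(table, categorical, group = "group",
                             correct = FALSE) {
  gv <- table[[group]]
  cv <- table[[categorical]]
  if (!is.factor(gv)) gv <- factor(gv)
  if (!is.factor(cv)) cv <- factor(cv)   # keep declared-but-empty levels
  tab <- base::table(gv, cv)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp == 0)) stopf("chi-square: zero expected cell count")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  c(chisq = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value)
}

#' ANCOVA group comparison adjusted for covariates
#'
#' Fits `outcome ~ group + covariates` by least squares; the group effect
#' is tested by the extra sum of squares between the covariate-only and the
#' full model. Adjusted group means are the model predictions at the grand
#' means of the covariates (sex encoded 0/1).
#'
#' @param table Data frame with `group`, covariates, and the outcome.
#' @param outcome Outcome column name.
#' @param covariates Covariate column names; a character `sex` column is
#'   encoded male = 1.
#' @param group Grouping column name.
#' @param subject_mean Average both eyes of each subject first
#'   (`subject_id` column required).
#' @return An `ancova_result` list: `outcome`, `n_per_group`,
#'   `adjusted_means`, `adjusted_diff` (first factor level minus second),
#'   `F`, `p`, `coefficients`.
#' @export
ancova <- function(table, outcome,
                   covariates = c("age", "sex", "axl_mm"),
                   group = "group", subject_mean = FALSE) {
  df <- table
  if (subject_mean) {
    if (!"subject_id" %in% names(df)) {
      stopf("ancova: subject_mean needs a subject_id column")
    }
    num <- c(outcome, setdiff(covariates, "sex"))
    agg <- stats::aggregate(df[num], by = list(subject_id = df$subject_id),
                            FUN = mean, na.rm = TRUE)
    meta <- df[!duplicated(df$subject_id),
               c("subject_id", group, intersect("sex", covariates))]
    df <- merge(agg, meta, by = "subject_id")
  }
  df <- df[stats::complete.cases(df[c(outcome, covariates, group)]), ]
  g <- factor(df[[group]])
  if (nlevels(g) != 2) stopf("ancova: need exactly two groups")
  X <- cbind(`(Intercept)` = 1, group = as.numeric(g == levels(g)[1]))
  for (cv in covariates) {
    v <- df[[cv]]
    if (!is.numeric(v)) v <- as.numeric(v == "male")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (nrow(X) < ncol(X) + 2) stopf("ancova: too few rows for the design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("ancova: rank-deficient design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  y <- df[[outcome]]
  fit_full <- stats::lm.fit(X, y)
  fit_red <- stats::lm.fit(X[, -2, drop = FALSE], y)
  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  df_res <- nrow(X) - ncol(X)
  Fstat <- (rss_red - rss_full) / (rss_full / df_res)
  p <- stats::pf(Fstat, 1, df_res, lower.tail = FALSE)
  beta <- fit_full$coefficients
  cov_means <- colMeans(X[, -(1:2), drop = FALSE])
  base <- unname(beta[1] + sum(beta[-(1:2)] * cov_means))
  adj <- c(base + beta[2], base)
  names(adj) <- levels(g)
  structure(
    list(outcome = outcome,
         n_per_group = stats::setNames(as.integer(base::table(g)), levels(g)),
         adjusted_means = adj,
         adjusted_diff = unname(beta[2]),
         F = Fstat, p = p,
         coefficients = beta),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: %s ~ group + covariates\n", x$outcome))
  cat(sprintf("  adjusted means: %s\n",
              paste(sprintf("%s = %.4g", names(x$adjusted_means),
                            x$adjusted_means), collapse = ", ")))
  cat(sprintf("  adjusted diff = %.4g, F = %.3f, p = %.4g (n = %s)\n",
              x$adjusted_diff, x$F, x$p,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

# display names of the nine parameters, in report order
.param_labels <- c(
  vdf = "Vascular fractal dimension",
  vt = "Vascular tortuosity (x10-3)",
  vd = "Vascular density (%)",
  vba_deg = "Vascular branching angle (deg)",
  vc_um = "Vascular caliber (um)",
  avr = "Arteriole to venule ratio",
  cup_area_mm2 = "Area of optic cup (mm2)",
  disc_area_mm2 = "Area of optic disc (mm2)",
  cdr = "Cup to disc ratio"
)

#' Cohort report tables (global, annulus, quadrant)
#'
#' Builds the three report shapes of a two-cohort comparison: per-parameter
#' group mean and SD plus the covariate-adjusted ANCOVA p value, globally
#' and per peripapillary annulus and quadrant. Missing scope/parameter
#' combinations yield `NA` cells rather than errors.
#'
#' @param metrics Data frame of per-eye metrics (one row per eye x scope)
#'   joined with covariates: columns `subject_id`, `eye`, `group`, `age`,
#'   `sex`, `axl_mm`, `scope`, and the parameter columns of
#'   [compute_metrics()].
#' @param covariates ANCOVA covariates.
#' @return `list(global, annulus, quadrant)` of data frames with columns
#'   `parameter`, `scope`, per-group `mean`/`sd`, and `p`.
#' @export
report_tables <- function(metrics, covariates = c("age", "sex", "axl_mm")) {
  groups <- sort(unique(metrics$group), decreasing = FALSE)
  mk <- function(scopes, params) {
    rows <- list()
    for (sc in scopes) {
      sub <- metrics[metrics$scope == sc, , drop = FALSE]
      for (pm in params) {
        row <- data.frame(parameter = unname(.param_labels[pm]), scope = sc,
                          stringsAsFactors = FALSE)
        for (gp in groups) {
          x <- sub[[pm]][sub$group == gp]
          x <- x[!is.na(x)]
          row[[paste0(gp, "_mean")]] <- if (length(x)) mean(x) else NA_real_
          row[[paste0(gp, "_sd")]] <- if (length(x) >= 2) stats::sd(x) else NA_real_
        }
        row$p <- tryCatch(
          ancova(sub, pm, covariates = covariates)$p,
          error = function(e) NA_real_
        )
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (length(rows) == 0) {
      return(data.frame(parameter = character(), scope = character(),
                        p = numeric(), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  all_params <- names(.param_labels)
  zone_params <- c("vdf", "vc_um", "vt", "vd")
  annuli <- intersect(.annulus_labels, unique(metrics$scope))
  quads <- intersect(.quadrant_labels, unique(metrics$scope))
  list(
    global = mk(intersect("global", unique(metrics$scope)), all_params),
    annulus = mk(annuli, zone_params),
    quadrant = mk(quads, zone_params)
  )
}
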