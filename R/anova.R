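# SBP-category assignment and two-way (sex x SBP category) ANOVA on
# unbalanced cohorts, with Table-style group summaries.

#' Assign the SBP category
#'
#' Readings are rounded half-up to integers first (auscultatory
#' pressures are integer-valued in practice), then binned:
#' `<=110`, `111-120`, `121-130`, `>=131` mmHg.
#'
#' @param sbp numeric systolic pressures (mmHg), all > 0.
#' @param round_first round half-up to integer before binning.
#' @return ordered factor with the four category levels.
#' @export
assign_sbp_category <- function(sbp, round_first = TRUE) {
  if (any(!is.finite(sbp)) || any(sbp <= 0))
    stop("`sbp` must be positive and finite", call. = FALSE)
  v <- if (round_first) round_half_up(sbp) else sbp
  lab <- ifelse(v <= 110, SBP_LEVELS[1],
         ifelse(v <= 120, SBP_LEVELS[2],
         ifelse(v <= 130, SBP_LEVELS[3], SBP_LEVELS[4])))
  factor(lab, levels = SBP_LEVELS, ordered = TRUE)
}

# Significance bucket used in the report tables.
p_bucket <- function(p) {
  ifelse(p < 0.01, "P<0.01", ifelse(p < 0.05, "P<0.05", "NS"))
}

#' Two-way ANOVA for sex and SBP category
#'
#' Fits `response ~ sex * sbp_category` with sum-to-zero factor coding
#' and reports F, degrees of freedom and p for both main effects and
#' the interaction.  Type III sums of squares are the default for the
#' unbalanced layout; Type II is available.  For balanced designs both
#' coincide with the classical closed form.
#'
#' A response with zero variance yields F = 0 and p = 1 for all effects
#' (no between-group variation to test).
#'
#' @param table a cohort table: data frame with factors `sex` and
#'   `sbp_category` and the response column.
#' @param response name of the response column.
#' @param type sum-of-squares type, 3 (default) or 2.
#' @param alpha significance threshold for the `significant` flag.
#' @return a data frame of class `anova_result` with one row per effect
#'   (`sex`, `sbp_category`, `sex:sbp_category`): `F`, `df1`, `df2`,
#'   `p`, `bucket`, `significant`.
#' @export
two_way_anova <- function(table, response, type = 3, alpha = 0.05) {
  if (!all(c("sex", "sbp_category") %in% names(table)))
    stop("`table` must have `sex` and `sbp_category` columns", call. = FALSE)
  if (!response %in% names(table))
    stop(sprintf("response `%s` not found", response), call. = FALSE)
  d <- data.frame(y = table[[response]],
                  sex = factor(table$sex),
                  cat = factor(table$sbp_category, ordered = FALSE))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$sex)) < 2 || nlevels(droplevels(d$cat)) < 2)
    stop("need at least 2 observed levels per factor", call. = FALSE)
  d$sex <- droplevels(d$sex); d$cat <- droplevels(d$cat)
  counts <- table(d$sex, d$cat)
  if (any(counts == 0))
    stop("design error: empty sex x SBP-category cell(s) make the layout rank-deficient",
         call. = FALSE)
  effects <- c("sex", "sbp_category", "sex:sbp_category")
  df2 <- nrow(d) - nlevels(d$sex) * nlevels(d$cat)
  if (df2 <= 0)
    stop("design error: no residual degrees of freedom (need more than one subject per cell)",
         call. = FALSE)
  if (stats::var(d$y) == 0) {
    out <- data.frame(effect = effects,
                      F = 0, df1 = c(nlevels(d$sex) - 1, nlevels(d$cat) - 1,
                                     (nlevels(d$sex) - 1) * (nlevels(d$cat) - 1)),
                      df2 = df2, p = 1)
  } else {
    contrasts(d$sex) <- stats::contr.sum(nlevels(d$sex))
    contrasts(d$cat) <- stats::contr.sum(nlevels(d$cat))
    fit <- stats::lm(y ~ sex * cat, data = d)
    a <- car::Anova(fit, type = type)
    rows <- c("sex", "cat", "sex:cat")
    out <- data.frame(effect = effects,
                      F = a[rows, "F value"],
                      df1 = a[rows, "Df"],
                      df2 = a["Residuals", "Df"],
                      p = a[rows, "Pr(>F)"])
  }
  out$bucket <- p_bucket(out$p)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Group summaries in the layout of the cohort tables
#'
#' Mean, SD and count per sex x SBP-category cell for each requested
#' variable.  Cells with a single subject report SD 0 and are flagged.
#'
#' @param table cohort table with `sex` and `sbp_category` factors.
#' @param variables character vector of column names to summarize.
#' @return a long data frame: `variable`, `sex`, `sbp_category`, `n`,
#'   `mean`, `sd`, `single_subject`.
#' @export
group_summary <- function(table, variables) {
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    stop(sprintf("variables not in table: %s", paste(missing_vars, collapse = ", ")),
         call. = FALSE)
  cells <- expand.grid(sbp_category = levels(factor(table$sbp_category)),
                       sex = levels(factor(table$sex)),
                       stringsAsFactors = FALSE)[, c("sex", "sbp_category")]
  out <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- table$sex == cells$sex[i] & table$sbp_category == cells$sbp_category[i]
      x <- table[[v]][sel]
      n <- sum(sel)
      data.frame(variable = v, sex = cells$sex[i], sbp_category = cells$sbp_category[i],
                 n = n,
                 mean = if (n) mean(x) else NA_real_,
                 sd = if (n >= 2) stats::sd(x) else if (n == 1) 0 else NA_real_,
                 single_subject = n == 1)
    }))
  }))
  if (any(out$single_subject, na.rm = TRUE))
    warning("some cells contain a single subject; their SD is reported as 0",
            call. = FALSE)
  rownames(out) <- NULL
  out
}
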