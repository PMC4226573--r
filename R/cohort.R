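# Subject-level cohort synthesis: draws wave-reflection indices and
# blood pressures per sex x SBP-category cell.

SBP_LEVELS <- c("<=110", "111-120", "121-130", ">=131")
SEX_LEVELS <- c("men", "women")
INDEX_VARS <- c("C1", "C2", "C_ref_forw", "H1", "H2", "H_ref_forw")

#' Specification of a synthetic subject cohort
#'
#' `cells` is a data frame with one row per sex x SBP-category cell,
#' holding the cell size `n` and a `<var>_mean` / `<var>_sd` column pair
#' for every generated variable (the six wave-reflection indices plus
#' `sbp` and `dbp`).
#'
#' @param cells cell-parameter data frame (see [reference_cohort_spec()]
#'   for the expected layout).
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells, seed = 1L) {
  req <- c("sex", "sbp_category", "n")
  if (!is.data.frame(cells) || !all(req %in% names(cells)))
    stop("`cells` must be a data frame with columns sex, sbp_category, n", call. = FALSE)
  if (any(cells$n < 1)) stop("all cell sizes must be >= 1", call. = FALSE)
  sds <- grep("_sd$", names(cells), value = TRUE)
  if (any(as.matrix(cells[sds]) < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (!all(cells$sex %in% SEX_LEVELS)) stop("sex must be 'men' or 'women'", call. = FALSE)
  if (!all(cells$sbp_category %in% SBP_LEVELS))
    stop(sprintf("sbp_category must be one of: %s", paste(SBP_LEVELS, collapse = ", ")), call. = FALSE)
  structure(list(cells = cells, seed = as.integer(seed)), class = "cohort_spec")
}

#' Built-in reference cohort parameterization
#'
#' The default simulation conditions: cell sizes, blood pressures and
#' wave-reflection index means/SDs of a 190-subject radial-artery cohort
#' stratified by sex and by four systolic-pressure categories
#' (<=110, 111-120, 121-130, >=131 mmHg).  These figures parameterize
#' the generator; they are not re-estimated by it.
#'
#' @param seed integer seed stored in the returned spec.
#' @return a [cohort_spec()].
#' @export
reference_cohort_spec <- function(seed = 1L) {
  g <- expand.grid(sbp_category = SBP_LEVELS, sex = SEX_LEVELS,
                   stringsAsFactors = FALSE)[, c("sex", "sbp_category")]
  cells <- data.frame(
    g,
    n = c(22, 29, 33, 21,  17, 25, 25, 18),
    sbp_mean = c(104, 115, 126, 135,  104, 116, 125, 134),
    sbp_sd   = c(3, 4, 3, 5,  4, 3, 3, 3),
    dbp_mean = c(67, 73, 77, 82,  66, 72, 75, 80),
    dbp_sd   = c(8, 7, 6, 7,  6, 8, 7, 6),
    C1_mean = c(136, 135, 140, 138,  142, 135, 137, 134),
    C1_sd   = c(11, 12, 11, 12,  9, 11, 11, 10),
    C2_mean = c(260, 251, 246, 233,  265, 256, 248, 235),
    C2_sd   = c(16, 12, 13, 14,  15, 14, 15, 15),
    C_ref_forw_mean = c(124, 116, 106, 95,  123, 121, 111, 101),
    C_ref_forw_sd   = c(16, 17, 11, 12,  15, 18, 17, 15),
    H1_mean = c(0.73, 0.70, 0.66, 0.61,  0.71, 0.70, 0.67, 0.62),
    H1_sd   = c(0.11, 0.12, 0.12, 0.13,  0.12, 0.12, 0.13, 0.10),
    H2_mean = c(0.67, 0.71, 0.73, 0.77,  0.67, 0.70, 0.72, 0.75),
    H2_sd   = c(0.10, 0.09, 0.11, 0.10,  0.11, 0.11, 0.09, 0.11),
    H_ref_forw_mean = c(92, 101, 111, 126,  94, 100, 107, 121),
    H_ref_forw_sd   = c(16, 17, 18, 20,  17, 17, 19, 19)
  )
  cohort_spec(cells, seed = seed)
}

# SBP-category bounds on the (integer-rounded) mmHg scale, half-open.
category_bounds <- function(cat) {
  switch(cat,
         "<=110"   = c(-Inf, 110.49),
         "111-120" = c(110.5, 120.49),
         "121-130" = c(120.5, 130.49),
         ">=131"   = c(130.5, Inf))
}

# Truncated-normal draw via inverse CDF, vectorized, deterministic under
# the caller's RNG state.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic subject cohort
#'
#' For each cell of the spec, draws the cell's `n` subjects' indices
#' independently from normal distributions with the cell's mean and SD.
#' SBP is drawn from a normal truncated to the cell's category range so
#' that the attached `sbp_category` label is always consistent with the
#' drawn pressure under the category-assignment rule.
#'
#' @param spec a [cohort_spec()], e.g. from [reference_cohort_spec()].
#' @return a data frame (`cohort_table`) with one row per subject:
#'   `subject_id`, `sex`, `sbp_category` (ordered factor), `sbp`, `dbp`,
#'   and the six wave-reflection indices.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  cells <- spec$cells
  vars <- sub("_mean$", "", grep("_mean$", names(cells), value = TRUE))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      cell <- cells[i, ]
      n <- cell$n
      out <- data.frame(sex = rep(cell$sex, n),
                        sbp_category = rep(cell$sbp_category, n),
                        stringsAsFactors = FALSE)
      for (v in vars) {
        m <- cell[[paste0(v, "_mean")]]
        s <- cell[[paste0(v, "_sd")]]
        if (v == "sbp") {
          b <- category_bounds(cell$sbp_category)
          out[[v]] <- rtruncnorm(n, m, s, b[1], b[2])
        } else if (s > 0) {
          out[[v]] <- stats::rnorm(n, m, s)
        } else {
          out[[v]] <- rep(m, n)
        }
      }
      if (all(c("sbp", "dbp") %in% names(out)))
        out$dbp <- pmin(out$dbp, out$sbp - 5)   # keep DBP below SBP
      out
    })
    tbl <- do.call(rbind, rows)
    tbl <- data.frame(subject_id = sprintf("S%03d", seq_len(nrow(tbl))), tbl,
                      stringsAsFactors = FALSE)
    tbl$sex <- factor(tbl$sex, levels = SEX_LEVELS)
    tbl$sbp_category <- factor(tbl$sbp_category, levels = SBP_LEVELS, ordered = TRUE)
    class(tbl) <- c("cohort_table", "data.frame")
    tbl
  })
}
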