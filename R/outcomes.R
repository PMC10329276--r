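#' Body mass index
#'
#' @param weight_kg body weight in kilograms (`> 0`).
#' @param height_m height in meters (`> 0`).
#' @return `weight / height^2` in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be positive")
  if (any(weight_kg <= 0)) stop("weight must be positive")
  weight_kg / height_m^2
}

#' Kolment four-level knee-function grade
#'
#' Grades knee function from range of motion (ROM) and pain frequency:
#' excellent iff ROM exceeds 120 degrees with no pain; good iff ROM is in
#' `[90, 120]` with at most occasional mild pain; poor iff ROM is 60 degrees
#' or less (see Details) or pain is frequent/constant; otherwise
#' intermediate (ROM above 60 with frequent mild pain, or a ROM/pain
#' combination that fails a higher grade). Exactly one grade is returned for
#' every input, with precedence excellent > good > intermediate > poor.
#'
#' @details The published criteria require ROM strictly greater than 60 for
#' intermediate and strictly less than 60 for poor, leaving exactly 60
#' unassigned; this implementation assigns it to poor.
#'
#' @param rom_degrees knee range of motion in degrees (`>= 0`), vectorized.
#' @param pain_category one of [pain_levels()], recycled against `rom`.
#' @return character vector of grades (see [kolment_levels()]).
#' @export
kolment_grade <- function(rom_degrees, pain_category) {
  if (any(rom_degrees < 0)) stop("rom must be nonnegative")
  if (!all(pain_category %in% pain_levels()))
    stop("unknown pain category: ",
         paste(setdiff(pain_category, pain_levels()), collapse = ", "))
  n <- max(length(rom_degrees), length(pain_category))
  rom <- rep_len(rom_degrees, n)
  pain <- rep_len(pain_category, n)
  out <- rep("poor", n)
  out[rom > 60 & pain != "frequent_or_constant"] <- "intermediate"
  out[rom >= 90 & rom <= 120 &
        pain %in% c("none", "occasional_mild")] <- "good"
  out[rom > 120 & pain == "none"] <- "excellent"
  out
}

#' Grade counts for one arm at one timepoint
#'
#' @param excellent,good,intermediate,poor nonnegative integer counts.
#' @param timepoint `"6m"` or `"12m"`.
#' @param arm arm label.
#' @return an object of class `grade_counts` with a `total` field.
#' @export
grade_counts <- function(excellent, good, intermediate, poor,
                         timepoint = "6m", arm = "") {
  counts <- c(excellent = excellent, good = good,
              intermediate = intermediate, poor = poor)
  stopifnot(all(counts >= 0), all(counts == as.integer(counts)))
  structure(list(counts = counts, total = sum(counts),
                 timepoint = timepoint, arm = arm),
            class = "grade_counts")
}

#' Excellent rate of a grade distribution
#'
#' `100 * (excellent + good) / total`, the headline outcome percentage.
#'
#' @param counts a [grade_counts()] object, or a length-4 vector of counts
#'   (excellent, good, intermediate, poor).
#' @return percentage in `[0, 100]`.
#' @export
excellent_rate <- function(counts) {
  if (inherits(counts, "grade_counts")) counts <- counts$counts
  stopifnot(length(counts) == 4, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  100 * (counts[[1]] + counts[[2]]) / total
}

#' Two-sample t test from summary statistics
#'
#' Two-sided test of equal means from per-group mean, standard deviation and
#' size. The default is the classical pooled-variance Student test with
#' `df = n1 + n2 - 2`; `var_equal = FALSE` gives the Welch test with
#' Satterthwaite degrees of freedom. With both standard deviations zero the
#' result degenerates: equal means give `t = 0, p = 1`, unequal means give
#' an infinite statistic and `p = 0`.
#'
#' @param mean1,sd1,n1 first group summary (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 second group summary.
#' @param var_equal pool the variances (default) or use Welch's correction.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with `E = rowsum * colsum / total`,
#' `df = (rows - 1)(cols - 1)` and an upper-tail p-value, without continuity
#' correction.
#'
#' @param table matrix of nonnegative counts with no all-zero row or column.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), nrow(table) >= 2, ncol(table) >= 2)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero expected cell counts; pool empty categories before testing")
  E <- outer(rs, cs) / sum(table)
  chisq <- sum((table - E)^2 / E)
  df <- as.integer((nrow(table) - 1) * (ncol(table) - 1))
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

format_mean_sd <- function(x) {
  sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
}

comparison_row <- function(variable, small, common, var_equal) {
  res <- two_sample_t(mean(small), stats::sd(small), length(small),
                      mean(common), stats::sd(common), length(common),
                      var_equal = var_equal)
  data.frame(variable = variable,
             small_incision = format_mean_sd(small),
             common = format_mean_sd(common),
             test = if (var_equal) "t (pooled)" else "t (Welch)",
             statistic = res$t, df = res$df, p_value = res$p,
             significant = res$p < 0.05,
             stringsAsFactors = FALSE)
}

grade_table_for <- function(cohort, timepoint) {
  rom_col <- paste0("rom_", timepoint, "_deg")
  pain_col <- paste0("pain_", timepoint)
  grades <- kolment_grade(cohort[[rom_col]], cohort[[pain_col]])
  t(vapply(c(small_incision = "small_incision", common = "common"),
           function(g) {
             tab <- table(factor(grades[cohort$group == g],
                                 levels = kolment_levels()))
             as.numeric(tab)
           }, numeric(4)))
}

#' Compare the two surgical arms of a cohort
#'
#' Reproduces the two-arm comparison tables from a cohort in the
#' [make_cohort()] schema: every continuous outcome (age, BMI, operation
#' time, blood loss, full weight-bearing time, healing time, ROM at 6 and 12
#' months) is tested with [two_sample_t()]; Kolment grades are derived from
#' the ROM/pain columns at each timepoint with [kolment_grade()],
#' summarized as counts and excellent rates, and tested with
#' [chi_square_test()] on the collapsed 2x2 table (excellent+good versus
#' intermediate+poor) to keep expected counts away from zero at clinical
#' sample sizes; `collapse = FALSE` tests the full 2x4 table instead.
#'
#' @param cohort cohort data frame with both arms non-empty.
#' @param var_equal use the pooled t test (default) or Welch.
#' @param collapse collapse grades to (excellent+good) vs rest for the
#'   chi-square test.
#' @param out optional CSV path for the comparison table.
#' @return list with `comparison` (one row per variable; columns `variable`,
#'   `small_incision`, `common`, `test`, `statistic`, `df`, `p_value`,
#'   `significant`) and `grades` (one row per arm and timepoint with counts
#'   and the excellent rate).
#' @export
compare_groups <- function(cohort, var_equal = TRUE, collapse = TRUE,
                           out = NULL) {
  needed <- c("group", "age_years", "bmi", "op_time_min", "blood_loss_ml",
              "full_load_weeks", "healing_weeks", "rom_6m_deg", "pain_6m",
              "rom_12m_deg", "pain_12m")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  small <- cohort[cohort$group == "small_incision", ]
  common <- cohort[cohort$group == "common", ]
  if (nrow(small) == 0 || nrow(common) == 0)
    stop("both arms must be non-empty")

  vars <- c(age_years = "age (years)", bmi = "BMI (kg/m2)",
            op_time_min = "operation time (min)",
            blood_loss_ml = "blood loss (mL)",
            full_load_weeks = "full weight-bearing time (weeks)",
            healing_weeks = "healing time (weeks)",
            rom_6m_deg = "ROM at 6 months (degrees)",
            rom_12m_deg = "ROM at 12 months (degrees)")
  comparison <- do.call(rbind, lapply(names(vars), function(v) {
    comparison_row(vars[[v]], small[[v]], common[[v]], var_equal)
  }))

  grades <- NULL
  for (tp in c("6m", "12m")) {
    tab <- grade_table_for(cohort, tp)
    test_tab <- if (collapse) {
      cbind(tab[, 1] + tab[, 2], tab[, 3] + tab[, 4])
    } else {
      tab[, colSums(tab) > 0, drop = FALSE]
    }
    ct <- if (any(colSums(test_tab) == 0) || ncol(test_tab) < 2) {
      # every patient in both arms falls in the same (collapsed) category:
      # the arms are trivially homogeneous on this outcome
      list(chisq = 0, df = NA_integer_, p = 1)
    } else {
      chi_square_test(test_tab)
    }
    comparison <- rbind(comparison, data.frame(
      variable = paste0("Kolment grade at ", tp,
                        if (collapse) " (excellent+good vs rest)" else ""),
      small_incision = paste(tab["small_incision", ], collapse = "/"),
      common = paste(tab["common", ], collapse = "/"),
      test = "chi-square", statistic = ct$chisq, df = ct$df,
      p_value = ct$p, significant = ct$p < 0.05,
      stringsAsFactors = FALSE))
    for (arm in rownames(tab)) {
      grades <- rbind(grades, data.frame(
        arm = arm, timepoint = tp,
        excellent = tab[arm, 1], good = tab[arm, 2],
        intermediate = tab[arm, 3], poor = tab[arm, 4],
        excellent_rate = round(excellent_rate(tab[arm, ]), 2),
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(out)) utils::write.csv(comparison, out, row.names = FALSE)
  list(comparison = comparison, grades = grades)
}
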