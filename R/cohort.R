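#' Masculinity index of a skeletal assemblage
#'
#' Number of males per 1000 females, rounded to the nearest integer
#' (half away from zero). Probable males count as males and probable
#' females as females. A cohort of 132 males and 65 females gives 2031.
#'
#' @param males Count of male or probably male individuals.
#' @param females Count of female or probably female individuals; must be
#'   positive, otherwise the index is undefined and an error is raised.
#' @return Integer index.
#' @examples
#' masculinity_index(132, 65)  # 2031
#' @export
masculinity_index <- function(males, females) {
  males <- as.numeric(males)
  females <- as.numeric(females)
  if (is.na(males) || is.na(females) || males < 0 || females < 0) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  if (females == 0) {
    stop("masculinity index undefined: no female individuals", call. = FALSE)
  }
  as.integer(floor(1000 * males / females + 0.5))
}

#' Subadult fraction of a cohort
#'
#' @param n_subadult Number of individuals who died at subadult age.
#' @param n_total Total cohort size, positive.
#' @return Percentage, rounded to one decimal. For 61 subadults of 217
#'   individuals this is 28.1.
#' @examples
#' subadult_fraction(61, 217)  # 28.1
#' @export
subadult_fraction <- function(n_subadult, n_total) {
  n_subadult <- as.numeric(n_subadult)
  n_total <- as.numeric(n_total)
  if (is.na(n_subadult) || is.na(n_total) || n_subadult < 0 ||
        n_total <= 0 || n_subadult > n_total) {
    stop("need 0 <= n_subadult <= n_total and n_total > 0", call. = FALSE)
  }
  round(100 * n_subadult / n_total, 1)
}

#' Assemblage-level demographic and classification summary
#'
#' Aggregates per-individual classifications and record metadata into
#' the counts the diagnostic study reports: sex composition and
#' masculinity index, subadult fraction, mean skeletal completeness,
#' positives by cultural assignment and the trait-count histogram.
#'
#' An individual is counted as subadult when the upper bound of its age
#' range is below \code{subadult_cutoff} (default 18 years).
#'
#' @param x An \code{\link{assemblage}}.
#' @param scores An \code{\link{classify}} result aligned with \code{x};
#'   computed with default settings when omitted.
#' @param subadult_cutoff Age in years below which an individual counts
#'   as subadult.
#' @return A list of class \code{"cohort_summary"} with elements
#'   \code{n_individuals}, \code{sex_counts} (males, females,
#'   undetermined, with probable sexes folded in), \code{masculinity_index}
#'   (NA when no females), \code{subadult_fraction},
#'   \code{completeness_mean}, \code{positives_by_culture} (named vector
#'   over cultures with at least one positive) and
#'   \code{trait_count_histogram} (named vector over 0..6).
#' @examples
#' cs <- cohort_summary(load_fixture())
#' cs$positives_by_culture[["yamnaya"]]  # 5
#' @export
cohort_summary <- function(x, scores = NULL, subadult_cutoff = 18) {
  stopifnot(inherits(x, "assemblage"))
  if (is.null(scores)) scores <- classify(x)
  if (!inherits(scores, "hs_scores") ||
      !identical(scores$individual_id, x$individual_id)) {
    stop("scores must be a classify() result aligned with the assemblage",
         call. = FALSE)
  }
  n <- nrow(x)
  males <- sum(x$sex %in% c("male", "probable_male"))
  females <- sum(x$sex %in% c("female", "probable_female"))
  undet <- sum(x$sex == "undetermined")
  mi <- if (females > 0) masculinity_index(males, females) else NA_integer_
  subad <- if (n > 0) subadult_fraction(sum(x$age_high < subadult_cutoff), n)
           else NA_real_
  pos_by_culture <- if (any(scores$positive)) {
    tab <- table(x$culture[scores$positive])
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  hist_ <- table(factor(scores$trait_count, levels = 0:6))
  out <- list(
    n_individuals = n,
    sex_counts = c(males = males, females = females, undetermined = undet),
    masculinity_index = mi,
    subadult_fraction = subad,
    completeness_mean = if (n > 0) mean(x$completeness) else NA_real_,
    positives_by_culture = pos_by_culture,
    trait_count_histogram = stats::setNames(as.integer(hist_), names(hist_)),
    subadult_cutoff = subadult_cutoff
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d individual(s)\n", x$n_individuals))
  cat(sprintf("  sex: %d male, %d female, %d undetermined\n",
              x$sex_counts[["males"]], x$sex_counts[["females"]],
              x$sex_counts[["undetermined"]]))
  if (!is.na(x$masculinity_index)) {
    cat(sprintf("  masculinity index: %d males per 1000 females\n",
                x$masculinity_index))
  } else {
    cat("  masculinity index: undefined (no females)\n")
  }
  if (!is.na(x$subadult_fraction)) {
    cat(sprintf("  subadult (< %g y): %.1f%%\n", x$subadult_cutoff,
                x$subadult_fraction))
  }
  if (!is.na(x$completeness_mean)) {
    cat(sprintf("  mean completeness: %.1f%%\n", x$completeness_mean))
  }
  tot <- sum(x$positives_by_culture)
  cat(sprintf("  positives: %d", tot))
  if (tot > 0) {
    cat(" (", paste(sprintf("%s: %d", names(x$positives_by_culture),
                            x$positives_by_culture), collapse = ", "),
        ")", sep = "")
  }
  cat("\n  trait-count histogram:",
      paste(sprintf("%s:%d", names(x$trait_count_histogram),
                    x$trait_count_histogram), collapse = " "), "\n")
  invisible(x)
}
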