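#' Classification thresholds for the dual diagnostic rule
#'
#' The diagnostic rule classifies an individual as a probable habitual
#' rider when both thresholds are met: at least \code{min_traits} of the
#' six diagnostic traits present (default 4, i.e. more than half) and a
#' weighted score of at least \code{min_points} out of the maximum 12
#' points (default 7, again more than half).
#'
#' @param min_traits Minimum number of present traits, in [0, 6].
#' @param min_points Minimum weighted score, in [0, 12].
#' @return A list of class \code{"hs_thresholds"}.
#' @export
hs_thresholds <- function(min_traits = 4L, min_points = 7L) {
  min_traits <- as.integer(min_traits)
  min_points <- as.integer(min_points)
  if (is.na(min_traits) || min_traits < 0L || min_traits > 6L) {
    stop("min_traits must be an integer in [0, 6]", call. = FALSE)
  }
  if (is.na(min_points) || min_points < 0L || min_points > 12L) {
    stop("min_points must be an integer in [0, 12]", call. = FALSE)
  }
  structure(list(min_traits = min_traits, min_points = min_points),
            class = "hs_thresholds")
}

#' @export
print.hs_thresholds <- function(x, ...) {
  cat(sprintf("Dual diagnostic thresholds: >= %d of 6 traits and >= %d of 12 points\n",
              x$min_traits, x$min_points))
  invisible(x)
}

#' Count present diagnostic traits
#'
#' @param x An \code{\link{assemblage}}.
#' @return A named integer vector (names are individual identifiers): the
#'   number of the six traits recorded as present. Absent and
#'   unobservable traits do not count.
#' @export
trait_count <- function(x) {
  m <- trait_states(x)
  n <- as.integer(rowSums(m == .state_present))
  names(n) <- rownames(m)
  n
}

#' Weighted base score
#'
#' Sums the catalog weights of the traits recorded as present. Absent
#' and unobservable (not preserved) traits contribute zero points:
#' missing evidence is never imputed, so poorly preserved skeletons can
#' only score lower, never higher, than fully observable ones (see
#' \code{\link{score_bounds}} for the resulting uncertainty interval).
#'
#' @param x An \code{\link{assemblage}}.
#' @param catalog Trait catalog; defaults to \code{\link{trait_catalog}}.
#' @return A named integer vector of scores in [0, 12].
#' @export
base_score <- function(x, catalog = trait_catalog()) {
  w <- .catalog_weights(catalog)
  m <- trait_states(x)
  s <- as.integer((m == .state_present) %*% w)
  names(s) <- rownames(m)
  s
}

#' Preservation-aware score bounds
#'
#' The base score is a lower bound on the score the individual would
#' receive were every trait observable: each unobservable trait could
#' contribute up to its full weight. \code{score_min} equals the base
#' score; \code{score_max} adds the weights of all unobservable traits.
#'
#' @inheritParams base_score
#' @return A data frame with columns \code{individual_id},
#'   \code{score_min} and \code{score_max}.
#' @export
score_bounds <- function(x, catalog = trait_catalog()) {
  w <- .catalog_weights(catalog)
  m <- trait_states(x)
  smin <- as.integer((m == .state_present) %*% w)
  smax <- smin + as.integer((m == .state_unobservable) %*% w)
  data.frame(individual_id = rownames(m), score_min = smin,
             score_max = smax, stringsAsFactors = FALSE)
}

#' Maximum attainable score given preservation
#'
#' The total weight of the traits that are observable (present or
#' absent), i.e. 12 minus the weight rendered unobservable by taphonomic
#' loss. An individual whose maximum attainable score falls below the
#' point threshold can never test positive no matter what the missing
#' regions would have shown.
#'
#' @inheritParams base_score
#' @return A named integer vector in [0, 12].
#' @export
max_attainable <- function(x, catalog = trait_catalog()) {
  w <- .catalog_weights(catalog)
  m <- trait_states(x)
  s <- as.integer((m != .state_unobservable) %*% w)
  names(s) <- rownames(m)
  s
}

#' Apply explicit severity deductions to base scores
#'
#' The published per-individual scores incorporate a
#' severity-of-expression adjustment whose exact rules are not public;
#' this function applies such an adjustment only as explicit input: a
#' table of non-negative per-trait deductions. A deduction is valid only
#' on a trait recorded as present and may not exceed that trait's weight,
#' so adjusted scores stay in [0, base score].
#'
#' @param x An \code{\link{assemblage}}.
#' @param deductions A data frame with columns \code{individual_id},
#'   \code{trait_id} and \code{deduction} (non-negative integers). May be
#'   empty.
#' @param catalog Trait catalog.
#' @return A named integer vector of adjusted scores, one per individual
#'   in \code{x} (individuals without deductions keep their base score).
#' @export
apply_adjustment <- function(x, deductions, catalog = trait_catalog()) {
  stopifnot(inherits(x, "assemblage"))
  base <- base_score(x, catalog)
  if (is.null(deductions) || nrow(deductions) == 0L) return(base)
  if (!all(c("individual_id", "trait_id", "deduction") %in% names(deductions))) {
    stop("deductions needs columns individual_id, trait_id, deduction",
         call. = FALSE)
  }
  w <- .catalog_weights(catalog)
  names(w) <- .trait_ids
  m <- trait_states(x)
  deductions$individual_id <- as.character(deductions$individual_id)
  for (i in seq_len(nrow(deductions))) {
    id <- deductions$individual_id[i]
    tid <- deductions$trait_id[i]
    d <- as.integer(deductions$deduction[i])
    if (!id %in% rownames(m)) {
      stop("deduction refers to unknown individual_id: ", id, call. = FALSE)
    }
    if (!tid %in% .trait_ids) {
      stop("deduction refers to unknown trait_id: ", tid, call. = FALSE)
    }
    if (is.na(d) || d < 0L) {
      stop("deduction must be a non-negative integer (individual ", id,
           ", trait ", tid, ")", call. = FALSE)
    }
    if (d > w[[tid]]) {
      stop("deduction exceeds trait weight (individual ", id, ", trait ",
           tid, ")", call. = FALSE)
    }
    if (m[id, tid] != .state_present) {
      stop("deduction on a trait that is not present (individual ", id,
           ", trait ", tid, ")", call. = FALSE)
    }
    base[[id]] <- base[[id]] - d
  }
  base
}

#' Classify an assemblage with the dual-threshold diagnostic rule
#'
#' Scores every individual and applies both thresholds: the trait-count
#' threshold (at least \code{min_traits} of 6 traits present) and the
#' point threshold (selected score at least \code{min_points} of 12).
#' An individual is positive — a probable habitual rider — only when
#' both are met.
#'
#' The point threshold can be applied to three score sources:
#' \describe{
#'   \item{\code{"base"}}{the weighted sum recomputed from the trait
#'     observations;}
#'   \item{\code{"reported"}}{the transcribed published score (which
#'     embeds an unpublished severity adjustment);}
#'   \item{\code{"adjusted"}}{the base score minus explicit deductions
#'     supplied via \code{deductions} (see
#'     \code{\link{apply_adjustment}});}
#'   \item{\code{"auto"}}{(default) the reported score where one exists,
#'     otherwise the base score; the source used is recorded per row.}
#' }
#' On the packaged 24-individual assemblage the base and reported sources
#' yield identical classifications.
#'
#' \code{preservation_capped} flags individuals whose classification
#' could change if their unobservable traits were preserved: currently
#' negative, but present-in-the-missing-regions completions would meet
#' both thresholds. The flag is advisory and never alters positivity.
#'
#' @param x An \code{\link{assemblage}}.
#' @param thresholds An \code{\link{hs_thresholds}} object.
#' @param score_source One of \code{"auto"}, \code{"base"},
#'   \code{"reported"}, \code{"adjusted"}.
#' @param deductions Deduction table, required for
#'   \code{score_source = "adjusted"}.
#' @param catalog Trait catalog.
#' @return A data frame of class \code{"hs_scores"} with one row per
#'   individual: \code{individual_id}, \code{trait_count},
#'   \code{base_score}, \code{score_min}, \code{score_max},
#'   \code{max_attainable}, \code{reported_score},
#'   \code{adjusted_score}, \code{score_used}, \code{source_used},
#'   \code{meets_trait_threshold}, \code{meets_point_threshold},
#'   \code{positive}, \code{preservation_capped}. Thresholds, score
#'   source and catalog version are carried as attributes.
#' @examples
#' res <- classify(load_fixture())
#' sum(res$positive)  # 9
#' @export
classify <- function(x, thresholds = hs_thresholds(),
                     score_source = c("auto", "base", "reported", "adjusted"),
                     deductions = NULL, catalog = trait_catalog()) {
  stopifnot(inherits(x, "assemblage"), inherits(thresholds, "hs_thresholds"))
  score_source <- match.arg(score_source)

  counts <- trait_count(x)
  base <- base_score(x, catalog)
  bounds <- score_bounds(x, catalog)
  maxat <- max_attainable(x, catalog)
  reported <- x$reported_score
  n_unobs <- as.integer(rowSums(trait_states(x) == .state_unobservable))

  adjusted <- rep(NA_integer_, nrow(x))
  if (score_source == "adjusted") {
    if (is.null(deductions)) {
      stop("score_source = \"adjusted\" requires a deductions table",
           call. = FALSE)
    }
    adjusted <- unname(apply_adjustment(x, deductions, catalog))
  }

  source_used <- switch(score_source,
    auto = ifelse(is.na(reported), "base", "reported"),
    base = rep("base", nrow(x)),
    reported = {
      if (anyNA(reported)) {
        stop("score_source = \"reported\" but reported_score missing for: ",
             paste(x$individual_id[is.na(reported)], collapse = ", "),
             call. = FALSE)
      }
      rep("reported", nrow(x))
    },
    adjusted = rep("adjusted", nrow(x)))

  score_used <- ifelse(source_used == "base", base,
                       ifelse(source_used == "reported", reported, adjusted))

  meets_traits <- counts >= thresholds$min_traits
  meets_points <- score_used >= thresholds$min_points
  positive <- meets_traits & meets_points

  ## Could a best-case completion of the unobservable traits flip a
  ## negative call? Computed from the base-score bounds (preservation is
  ## a property of the observations, not of the score source).
  capped <- !positive &
    (counts + n_unobs >= thresholds$min_traits) &
    (bounds$score_max >= thresholds$min_points)

  out <- data.frame(
    individual_id = x$individual_id,
    trait_count = unname(counts),
    base_score = unname(base),
    score_min = bounds$score_min,
    score_max = bounds$score_max,
    max_attainable = unname(maxat),
    reported_score = reported,
    adjusted_score = adjusted,
    score_used = as.integer(score_used),
    source_used = source_used,
    meets_trait_threshold = unname(meets_traits),
    meets_point_threshold = unname(meets_points),
    positive = unname(positive),
    preservation_capped = unname(capped),
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- thresholds
  attr(out, "score_source") <- score_source
  attr(out, "catalog_version") <- .catalog_version
  attr(out, "label") <- attr(x, "label")
  class(out) <- c("hs_scores", "data.frame")
  out
}

#' @export
print.hs_scores <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Horsemanship-syndrome classification (>= %d traits, >= %d points; source: %s)\n",
    th$min_traits, th$min_points, attr(x, "score_source")))
  print.data.frame(as.data.frame(
    x[, c("individual_id", "trait_count", "score_used", "source_used",
          "positive", "preservation_capped")]))
  invisible(x)
}

#' @export
summary.hs_scores <- function(object, ...) {
  th <- attr(object, "thresholds")
  cat(sprintf("%d individual(s); thresholds >= %d of 6 traits and >= %d of 12 points\n",
              nrow(object), th$min_traits, th$min_points))
  cat(sprintf("Positive (probable riders): %d\n", sum(object$positive)))
  if (any(object$positive)) {
    cat("  ", paste(object$individual_id[object$positive], collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("Preservation-capped negatives: %d\n",
              sum(object$preservation_capped)))
  invisible(object)
}

#' Platymeric index and femoral shaft shape category
#'
#' The platymeric index is 100 times the ratio of the anteroposterior to
#' the mediolateral subtrochanteric femoral shaft diameter. Values below
#' 85 indicate anteroposterior flattening (platymery), the standard
#' osteometric convention; boundary values fall in the upper category.
#'
#' @param ap Anteroposterior diameter (mm), positive.
#' @param ml Mediolateral diameter (mm), positive.
#' @return A data frame with columns \code{index} and \code{category}
#'   (\code{"platymeric"} if index < 85, \code{"eurymeric"} if
#'   85 <= index < 100, \code{"stenomeric"} otherwise).
#' @examples
#' platymeric_index(81.4, 100)  # platymeric, as in the index 81.4 femora
#' @export
platymeric_index <- function(ap, ml) {
  ap <- as.numeric(ap)
  ml <- as.numeric(ml)
  if (length(ap) != length(ml)) stop("ap and ml must have equal length",
                                     call. = FALSE)
  if (any(!is.finite(ap)) || any(!is.finite(ml)) || any(ap <= 0) ||
        any(ml <= 0)) {
    stop("diameters must be positive finite numbers", call. = FALSE)
  }
  idx <- 100 * ap / ml
  cat_ <- ifelse(idx < 85, "platymeric",
                 ifelse(idx < 100, "eurymeric", "stenomeric"))
  data.frame(index = idx, category = cat_, stringsAsFactors = FALSE)
}
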