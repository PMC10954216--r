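## Synthetic skeletal assemblages with known rider status, for
## quantifying the diagnostic rule's sensitivity/specificity under
## configurable trait prevalence and taphonomic loss.

#' Configuration for the synthetic assemblage generator
#'
#' Defines the generative model: each individual carries a latent rider
#' status (Bernoulli with \code{rider_fraction}); given status, each of
#' the six traits is present independently with the status-conditional
#' probability; preservation then masks each trait to unobservable,
#' independently of rider status. Two preservation models are supported:
#' a global per-trait observability vector, or a completeness-linked
#' model in which each skeleton draws a completeness percentage uniformly
#' from \code{completeness_range} and every trait is observable with
#' probability completeness/100 (traits of one skeleton then share their
#' preservation fate through the common completeness).
#'
#' The defaults mimic the structure of the published cohort: 217
#' individuals, completeness uniform on [20, 95] (mean 57.5, close to
#' the reported cohort mean of 57), 61\% males and a 28\% subadult
#' fraction. The rider fraction and the two trait-prevalence vectors are
#' illustrative only — no nonrider base rates for any trait have been
#' published, so all sensitivity/specificity results are conditional on
#' the rates supplied here.
#'
#' @param n_individuals Number of skeletons (>= 1).
#' @param rider_fraction Probability that an individual is a rider.
#' @param p_trait_rider Length-6 vector: per-trait presence probability
#'   given rider status (canonical trait order).
#' @param p_trait_nonrider Length-6 vector: per-trait presence
#'   probability given nonrider status.
#' @param preservation Either a length-6 numeric vector of per-trait
#'   observability probabilities, or the string \code{"completeness"}
#'   for the completeness-linked model.
#' @param completeness_range Length-2 numeric, percentage bounds for the
#'   completeness draw (used only by the completeness-linked model).
#' @param sex_male_fraction Probability that an individual is male.
#' @param subadult_fraction Probability that an individual died subadult.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A validated list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_individuals = 217L,
                             rider_fraction = 0.15,
                             p_trait_rider = c(0.9, 0.6, 0.8, 0.7, 0.7, 0.4),
                             p_trait_nonrider = c(0.30, 0.05, 0.20, 0.15,
                                                  0.25, 0.10),
                             preservation = "completeness",
                             completeness_range = c(20, 95),
                             sex_male_fraction = 0.61,
                             subadult_fraction = 0.281,
                             seed = 1L) {
  chk_prob <- function(v, nm, len = 1L) {
    if (length(v) != len || any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop(nm, " must be ", if (len > 1L) paste0("a length-", len, " vector of "),
           "probability(ies) in [0, 1]", call. = FALSE)
    }
  }
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) {
    stop("n_individuals must be an integer >= 1", call. = FALSE)
  }
  chk_prob(rider_fraction, "rider_fraction")
  chk_prob(p_trait_rider, "p_trait_rider", 6L)
  chk_prob(p_trait_nonrider, "p_trait_nonrider", 6L)
  if (is.character(preservation)) {
    if (!identical(preservation, "completeness")) {
      stop("preservation must be \"completeness\" or a length-6 probability vector",
           call. = FALSE)
    }
    if (length(completeness_range) != 2L || any(!is.finite(completeness_range)) ||
          completeness_range[1L] > completeness_range[2L] ||
          completeness_range[1L] < 0 || completeness_range[2L] > 100) {
      stop("completeness_range must be increasing and within [0, 100]",
           call. = FALSE)
    }
  } else {
    chk_prob(preservation, "preservation", 6L)
  }
  chk_prob(sex_male_fraction, "sex_male_fraction")
  chk_prob(subadult_fraction, "subadult_fraction")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(n_individuals = n_individuals,
                 rider_fraction = rider_fraction,
                 p_trait_rider = p_trait_rider,
                 p_trait_nonrider = p_trait_nonrider,
                 preservation = preservation,
                 completeness_range = completeness_range,
                 sex_male_fraction = sex_male_fraction,
                 subadult_fraction = subadult_fraction,
                 seed = seed),
            class = "synthetic_config")
}

## Deterministic substream seed: individual i (or replicate r) of a run
## gets its own RNG seed so that changing n_individuals never reshuffles
## earlier individuals.
.derive_seed <- function(seed, k) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 69621 + 1
  as.integer(v %% 2147483647)
}

#' Generate a synthetic skeletal assemblage
#'
#' Draws an assemblage from the generative model described in
#' \code{\link{synthetic_config}}. The latent rider status of every
#' individual is carried alongside the assemblage as the attribute
#' \code{"true_rider"} (see \code{\link{true_riders}}); it is not a
#' column and is not written by \code{\link{write_trait_table}}.
#'
#' Each individual consumes an independent, deterministically derived
#' RNG substream, so the first k individuals are identical across runs
#' that differ only in \code{n_individuals}.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return An \code{\link{assemblage}} with attribute
#'   \code{"true_rider"} (logical vector).
#' @export
generate_assemblage <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  n <- config$n_individuals
  global_pres <- !is.character(config$preservation)
  width <- max(3L, nchar(as.character(n)))

  rider <- logical(n)
  completeness <- numeric(n)
  sex <- character(n)
  age_low <- integer(n)
  age_high <- integer(n)
  states <- matrix(NA_character_, nrow = n, ncol = 6L)

  for (i in seq_len(n)) {
    set.seed(.derive_seed(config$seed, i))
    u <- stats::runif(17L)
    rider[i] <- u[1L] < config$rider_fraction
    if (global_pres) {
      q <- config$preservation
      completeness[i] <- round(100 * mean(q), 1)
    } else {
      completeness[i] <- config$completeness_range[1L] +
        diff(config$completeness_range) * u[2L]
      q <- rep(completeness[i] / 100, 6L)
    }
    p <- if (rider[i]) config$p_trait_rider else config$p_trait_nonrider
    present <- u[3L:8L] < p
    observed <- u[9L:14L] < q
    states[i, ] <- ifelse(!observed, .state_unobservable,
                          ifelse(present, .state_present, .state_absent))
    sex[i] <- if (u[15L] < config$sex_male_fraction) "male" else "female"
    if (u[16L] < config$subadult_fraction) {
      age_low[i] <- 5L + as.integer(floor(11 * u[17L]))   # 5..15
      age_high[i] <- age_low[i] + 2L
    } else {
      age_low[i] <- 18L + as.integer(floor(33 * u[17L]))  # 18..50
      age_high[i] <- age_low[i] + 10L
    }
  }

  df <- data.frame(
    individual_id = formatC(seq_len(n), width = width, flag = "0"),
    country = "XX",
    site_label = "synthetic",
    completeness = round(completeness, 1),
    sex = sex,
    age_low = age_low,
    age_high = age_high,
    culture = "other",
    stringsAsFactors = FALSE
  )
  for (j in seq_along(.trait_ids)) df[[.trait_ids[j]]] <- states[, j]
  out <- assemblage(df, label = "synthetic assemblage",
                    provenance = sprintf("synthetic seed %d", config$seed))
  attr(out, "true_rider") <- rider
  out
}

#' Latent rider labels of a synthetic assemblage
#'
#' @param x An assemblage produced by \code{\link{generate_assemblage}}.
#' @return Logical vector of true rider status, one per individual.
#' @export
true_riders <- function(x) {
  r <- attr(x, "true_rider")
  if (is.null(r)) {
    stop("assemblage carries no latent rider labels (not synthetic?)",
         call. = FALSE)
  }
  r
}

#' Monte-Carlo diagnostic performance of the dual-threshold rule
#'
#' Generates \code{n_reps} synthetic assemblages, classifies each with
#' the recomputed base score (\code{score_source = "base"}) and
#' aggregates the confusion totals against the latent rider labels.
#' Deterministic given the config seed: replicate r uses a seed derived
#' from it.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param thresholds An \code{\link{hs_thresholds}}.
#' @param n_reps Number of replicate assemblages (>= 1).
#' @return A list of class \code{"diagnostic_performance"}:
#'   \code{sensitivity}, \code{specificity}, \code{ppv} (each with a
#'   binomial Monte-Carlo standard error \code{*_se}; \code{NA} and
#'   flagged undefined when the relevant denominator is empty),
#'   \code{confusion} (TP, FP, TN, FN summed over replicates) and
#'   \code{n_reps}.
#' @export
estimate_performance <- function(config, thresholds = hs_thresholds(),
                                 n_reps = 100L) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  draws <- .simulate_draws(config, n_reps)
  .performance_from_draws(draws, thresholds, n_reps)
}

## One row per simulated individual over all replicates: trait count,
## base score, latent rider status.
.simulate_draws <- function(config, n_reps) {
  counts <- vector("list", n_reps)
  scores <- vector("list", n_reps)
  riders <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- .derive_seed(config$seed, 1000000L + r)
    a <- generate_assemblage(cfg_r)
    counts[[r]] <- unname(trait_count(a))
    scores[[r]] <- unname(base_score(a))
    riders[[r]] <- true_riders(a)
  }
  data.frame(trait_count = unlist(counts), base_score = unlist(scores),
             rider = unlist(riders))
}

.performance_from_draws <- function(draws, thresholds, n_reps) {
  pos <- draws$trait_count >= thresholds$min_traits &
    draws$base_score >= thresholds$min_points
  tp <- sum(pos & draws$rider)
  fp <- sum(pos & !draws$rider)
  tn <- sum(!pos & !draws$rider)
  fn <- sum(!pos & draws$rider)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  se <- function(p, den) if (den > 0 && !is.na(p)) sqrt(p * (1 - p) / den)
                         else NA_real_
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  structure(list(
    sensitivity = sens, sensitivity_se = se(sens, tp + fn),
    specificity = spec, specificity_se = se(spec, tn + fp),
    ppv = ppv, ppv_se = se(ppv, tp + fp),
    sensitivity_defined = (tp + fn) > 0,
    specificity_defined = (tn + fp) > 0,
    ppv_defined = (tp + fp) > 0,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    n_reps = n_reps,
    thresholds = thresholds
  ), class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "Diagnostic performance over %d replicate(s) (>= %d traits, >= %d points)\n",
    x$n_reps, th$min_traits, th$min_points))
  fmt <- function(v, s, def, nm) {
    if (def) cat(sprintf("  %-12s %.4f (MC se %.4f)\n", nm, v, s))
    else cat(sprintf("  %-12s undefined (empty denominator)\n", nm))
  }
  fmt(x$sensitivity, x$sensitivity_se, x$sensitivity_defined, "sensitivity")
  fmt(x$specificity, x$specificity_se, x$specificity_defined, "specificity")
  fmt(x$ppv, x$ppv_se, x$ppv_defined, "PPV")
  cat(sprintf("  confusion:   TP %d, FP %d, TN %d, FN %d\n",
              x$confusion[["TP"]], x$confusion[["FP"]],
              x$confusion[["TN"]], x$confusion[["FN"]]))
  invisible(x)
}

#' Exact positive-classification probability by enumeration
#'
#' For a single individual with per-trait presence probabilities
#' \code{p_traits} and per-trait observability probabilities
#' \code{preservation} (the global, trait-independent preservation
#' model), computes the exact probability of a positive classification
#' by enumerating all 3^6 = 729 observation outcomes. Per trait the
#' outcome probabilities are: present-and-observed \code{p*q},
#' observed-absent \code{(1-p)*q}, unobservable \code{1-q}.
#'
#' This is the enumeration oracle against which the Monte-Carlo
#' estimates of \code{\link{estimate_performance}} are checked; it does
#' not cover the completeness-linked preservation model, whose traits
#' are dependent through the shared completeness draw.
#'
#' @param p_traits Length-6 presence probabilities (canonical order).
#' @param preservation Length-6 observability probabilities.
#' @param thresholds An \code{\link{hs_thresholds}}.
#' @param catalog Trait catalog.
#' @return A probability.
#' @export
exact_positive_probability <- function(p_traits, preservation,
                                       thresholds = hs_thresholds(),
                                       catalog = trait_catalog()) {
  stopifnot(length(p_traits) == 6L, length(preservation) == 6L,
            all(p_traits >= 0 & p_traits <= 1),
            all(preservation >= 0 & preservation <= 1),
            inherits(thresholds, "hs_thresholds"))
  w <- .catalog_weights(catalog)
  ## outcome 1 = present & observed, 2 = observed absent, 3 = unobservable
  grid <- as.matrix(expand.grid(rep(list(1:3), 6L)))
  p_outcome <- rbind(p_traits * preservation,
                     (1 - p_traits) * preservation,
                     1 - preservation)
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(p_outcome[cbind(grid[i, ], seq_len(6L))])
  }, numeric(1L))
  present <- grid == 1L
  counts <- rowSums(present)
  scores <- as.numeric(present %*% w)
  positive <- counts >= thresholds$min_traits & scores >= thresholds$min_points
  sum(probs[positive])
}

#' Sensitivity/specificity over a grid of thresholds
#'
#' Evaluates the diagnostic rule on a grid of (trait threshold, point
#' threshold) pairs using common random numbers: the same
#' \code{n_reps} simulated assemblages are reused for every grid point,
#' so the positive set at a stricter pair is exactly a subset of the
#' positive set at a looser pair, and the sensitivity/specificity
#' columns are exactly monotone in each threshold.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param trait_grid Integer vector of trait-count thresholds.
#' @param point_grid Integer vector of point thresholds.
#' @param n_reps Number of replicate assemblages shared by all grid
#'   points.
#' @return A data frame of class \code{"hs_sweep"}: one row per grid
#'   pair with \code{min_traits}, \code{min_points}, confusion totals,
#'   \code{sensitivity} and \code{specificity}. The shared simulated
#'   draws are attached as attribute \code{"draws"}.
#' @export
threshold_sweep <- function(config, trait_grid = 0:6, point_grid = 0:12,
                            n_reps = 50L) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  trait_grid <- as.integer(trait_grid)
  point_grid <- as.integer(point_grid)
  if (length(trait_grid) == 0L || length(point_grid) == 0L) {
    stop("threshold grids must be non-empty", call. = FALSE)
  }
  draws <- .simulate_draws(config, as.integer(n_reps))
  rows <- expand.grid(min_traits = trait_grid, min_points = point_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    th <- hs_thresholds(rows$min_traits[i], rows$min_points[i])
    perf <- .performance_from_draws(draws, th, as.integer(n_reps))
    data.frame(min_traits = th$min_traits, min_points = th$min_points,
               TP = perf$confusion[["TP"]], FP = perf$confusion[["FP"]],
               TN = perf$confusion[["TN"]], FN = perf$confusion[["FN"]],
               sensitivity = perf$sensitivity,
               specificity = perf$specificity)
  })
  out <- do.call(rbind, res)
  attr(out, "draws") <- draws
  attr(out, "seed") <- config$seed
  class(out) <- c("hs_sweep", "data.frame")
  out
}
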