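# Independent brute-force oracles and small builders used across tests.
# These deliberately avoid the package's vectorised scoring path.

ORACLE_WEIGHTS <- c(3L, 3L, 2L, 2L, 1L, 1L)
TRAITS <- c("entheses", "ovalization", "lesion", "platymeric",
            "vertebral", "trauma")

# Sum weights of present traits by explicit loop.
bf_score <- function(states, weights = ORACLE_WEIGHTS) {
  s <- 0L
  for (j in seq_along(states)) {
    if (states[j] == "present") s <- s + weights[j]
  }
  s
}

# Min/max score over every completion of the unobservable traits.
bf_bounds <- function(states, weights = ORACLE_WEIGHTS) {
  unobs <- which(states == "unobservable")
  k <- length(unobs)
  scores <- integer(2^k)
  for (mask in 0:(2^k - 1)) {
    st <- states
    if (k > 0) {
      bits <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
      st[unobs] <- ifelse(bits, "present", "absent")
    }
    scores[mask + 1L] <- bf_score(st, weights)
  }
  c(min(scores), max(scores))
}

# All 3^6 = 729 observation vectors.
all_state_vectors <- function() {
  g <- expand.grid(rep(list(c("present", "absent", "unobservable")), 6),
                   stringsAsFactors = FALSE)
  names(g) <- TRAITS
  as.matrix(g)
}

# Minimal valid assemblage from a states matrix (words or +/-/? symbols).
mk_assemblage <- function(states, ids = NULL, reported = NA_integer_,
                          culture = "other", sex = "m") {
  if (is.vector(states)) states <- matrix(states, nrow = 1)
  n <- nrow(states)
  if (is.null(ids)) ids <- sprintf("%03d", seq_len(n))
  df <- data.frame(individual_id = ids, country = "XX", site_label = "test",
                   completeness = 50, sex = sex, age_low = 20L,
                   age_high = 30L, culture = culture,
                   reported_score = reported, stringsAsFactors = FALSE)
  for (j in seq_along(TRAITS)) df[[TRAITS[j]]] <- states[, j]
  assemblage(df, label = "test", provenance = "test")
}

# Random valid assemblage for round-trip properties.
random_assemblage <- function(n, seed) {
  set.seed(seed)
  states <- matrix(sample(c("present", "absent", "unobservable"), 6 * n,
                          replace = TRUE), nrow = n)
  df <- data.frame(
    individual_id = sprintf("%03d", seq_len(n)),
    country = sample(c("RO", "BG", "HU"), n, replace = TRUE),
    site_label = paste("site", seq_len(n)),
    completeness = round(stats::runif(n, 0, 100), 1),
    sex = sample(c("m", "(m)", "f", "(f)", ""), n, replace = TRUE),
    age_low = sample(5:40, n, replace = TRUE),
    age_high = sample(41:80, n, replace = TRUE),
    culture = sample(c("Yamnaya", "Pre-Yamnaya", "Corded Ware", "other"),
                     n, replace = TRUE),
    reported_score = ifelse(stats::runif(n) < 0.5,
                            sample(0:12, n, replace = TRUE), NA_integer_),
    stringsAsFactors = FALSE)
  for (j in seq_along(TRAITS)) df[[TRAITS[j]]] <- states[, j]
  assemblage(df, label = "random", provenance = "test")
}

# Content comparison ignoring label/provenance bookkeeping attributes.
plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "label") <- NULL
  attr(x, "provenance") <- NULL
  attr(x, "true_rider") <- NULL
  rownames(x) <- NULL
  x
}

# Frozen transcription checks (ids in sorted order).
FIXTURE_IDS <- c("032", "034", "064", "081", "082", "092", "103", "116",
                 "118", "130", "135", "148", "153", "161", "164", "166",
                 "170", "174", "177", "186", "198", "209", "213", "215")
FIXTURE_TRAIT_COUNTS <- c(4L, 3L, 6L, 3L, 3L, 3L, 3L, 4L, 5L, 3L, 3L, 3L,
                          5L, 4L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 5L, 5L, 4L)
FIXTURE_REPORTED <- c(7L, 5L, 12L, 5L, 5L, 3L, 5L, 7L, 10L, 6L, 4L, 3L,
                      9L, 7L, 4L, 6L, 7L, 6L, 6L, 7L, 3L, 9L, 10L, 7L)
FIXTURE_POSITIVE_IDS <- c("032", "064", "116", "118", "153", "161", "209",
                          "213", "215")
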