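## Assemblage: a validated data frame of skeletal individuals, one row per
## skeleton, with metadata columns plus one column per canonical trait
## holding the observation state ("present" / "absent" / "unobservable").

.sex_levels <- c("male", "probable_male", "female", "probable_female",
                 "undetermined")
.culture_levels <- c("yamnaya", "pre_yamnaya", "post_yamnaya", "corded_ware",
                     "copper_age", "middle_bronze_age", "other")

.required_cols <- c("individual_id", "country", "site_label", "completeness",
                    "sex", "age_low", "age_high", "culture")
.optional_cols <- c("culture_note", "radiocarbon", "reported_score")

#' Construct a skeletal assemblage
#'
#' An assemblage is an ordered collection of skeletal individuals with
#' their six diagnostic trait observations. It is represented as a data
#' frame of class \code{"assemblage"} with one row per individual and is
#' validated on construction: unique individual identifiers, completeness
#' in [0, 100], non-negative age ranges with \code{age_low <= age_high},
#' recognised sex and culture codes, and one of the three observation
#' states per trait.
#'
#' @param df A data frame with columns \code{individual_id},
#'   \code{country}, \code{site_label}, \code{completeness}, \code{sex},
#'   \code{age_low}, \code{age_high}, \code{culture}, the six canonical
#'   trait columns (\code{entheses}, \code{ovalization}, \code{lesion},
#'   \code{platymeric}, \code{vertebral}, \code{trauma}) and optionally
#'   \code{culture_note}, \code{radiocarbon} and \code{reported_score}.
#'   Trait states and sex/culture labels are normalised (see
#'   \code{\link{read_trait_table}} for the accepted symbols).
#' @param label Free-text label for the assemblage.
#' @param provenance Free-text provenance note (e.g. file path, fixture,
#'   or the seed of a synthetic draw).
#' @return A data frame of class \code{"assemblage"}.
#' @seealso \code{\link{load_fixture}}, \code{\link{read_trait_table}},
#'   \code{\link{generate_assemblage}}
#' @export
assemblage <- function(df, label = "", provenance = "") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  missing <- setdiff(c(.required_cols, .trait_ids), names(df))
  if (length(missing) > 0L) {
    stop("assemblage is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("culture_note", "radiocarbon")) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(NA_character_, nrow(df))
    } else {
      v <- as.character(df[[col]])
      v[!is.na(v) & v == ""] <- NA_character_
      df[[col]] <- v
    }
  }
  if (!"reported_score" %in% names(df)) {
    df$reported_score <- rep(NA_integer_, nrow(df))
  }

  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id)) {
    dup <- unique(df$individual_id[duplicated(df$individual_id)])
    stop("duplicate individual_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  df$completeness <- as.numeric(df$completeness)
  bad <- which(!is.finite(df$completeness) | df$completeness < 0 |
                 df$completeness > 100)
  if (length(bad) > 0L) {
    stop("completeness must lie in [0, 100]; offending individual_id: ",
         paste(df$individual_id[bad], collapse = ", "), call. = FALSE)
  }

  df$age_low <- as.integer(df$age_low)
  df$age_high <- as.integer(df$age_high)
  bad <- which(is.na(df$age_low) | is.na(df$age_high) |
                 df$age_low < 0 | df$age_low > df$age_high)
  if (length(bad) > 0L) {
    stop("age range must satisfy 0 <= age_low <= age_high; ",
         "offending individual_id: ",
         paste(df$individual_id[bad], collapse = ", "), call. = FALSE)
  }

  norm <- normalize_sex(df$sex)
  bad <- which(is.na(norm))
  if (length(bad) > 0L) {
    stop("unrecognised sex code(s): ",
         paste(unique(df$sex[bad]), collapse = ", "), call. = FALSE)
  }
  df$sex <- norm

  cl <- normalize_culture(df$culture)
  bad <- which(is.na(cl$culture))
  if (length(bad) > 0L) {
    stop("unrecognised culture label(s): ",
         paste(unique(df$culture[bad]), collapse = ", "), call. = FALSE)
  }
  note_missing <- is.na(df$culture_note) | df$culture_note == ""
  df$culture_note[note_missing] <- cl$note[note_missing]
  df$culture <- cl$culture

  for (tid in .trait_ids) {
    st <- .state_symbols_in[as.character(df[[tid]])]
    bad <- which(is.na(st))
    if (length(bad) > 0L) {
      stop(sprintf(
        "unrecognised observation state '%s' in trait column '%s' (individual_id %s)",
        df[[tid]][bad[1L]], tid, df$individual_id[bad[1L]]), call. = FALSE)
    }
    df[[tid]] <- unname(st)
  }

  raw <- df$reported_score
  if (is.character(raw)) raw[!is.na(raw) & trimws(raw) == ""] <- NA
  score <- suppressWarnings(as.integer(raw))
  bad <- which(!is.na(raw) & is.na(score))
  if (length(bad) > 0L) {
    stop("reported_score is not an integer; offending individual_id: ",
         paste(df$individual_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(score) & (score < 0L | score > 12L))
  if (length(bad) > 0L) {
    stop("reported_score must lie in [0, 12]; offending individual_id: ",
         paste(df$individual_id[bad], collapse = ", "), call. = FALSE)
  }
  df$reported_score <- score

  df <- df[, c(.required_cols[1L:8L], "culture_note", "radiocarbon",
               .trait_ids, "reported_score")]
  rownames(df) <- NULL
  attr(df, "label") <- as.character(label)
  attr(df, "provenance") <- as.character(provenance)
  class(df) <- c("assemblage", "data.frame")
  df
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("Skeletal assemblage: %d individual(s)\n", nrow(x)))
  if (nzchar(attr(x, "label") %||% "")) {
    cat("  label:     ", attr(x, "label"), "\n", sep = "")
  }
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("  provenance:", attr(x, "provenance"), "\n")
  }
  print.data.frame(utils::head(as.data.frame(
    x[, c("individual_id", "country", "completeness", "sex", "culture",
          .trait_ids)]), 10L))
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more row(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the trait state matrix of an assemblage
#'
#' @param x An \code{\link{assemblage}}.
#' @return A character matrix (individuals x 6 traits, canonical order)
#'   with entries \code{"present"}, \code{"absent"} or
#'   \code{"unobservable"}; row names are individual identifiers.
#' @export
trait_states <- function(x) {
  stopifnot(inherits(x, "assemblage"))
  m <- as.matrix(as.data.frame(x)[, .trait_ids, drop = FALSE])
  rownames(m) <- x$individual_id
  m
}

## Sex label normalisation: published-table codes and enum tokens.
normalize_sex <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "M", "male")] <- "male"
  out[x %in% c("(m)", "m?", "probable_male")] <- "probable_male"
  out[x %in% c("f", "F", "female")] <- "female"
  out[x %in% c("(f)", "f?", "probable_female")] <- "probable_female"
  out[x %in% c("", "u", "indet", "undetermined", NA)] <- "undetermined"
  out
}

## Culture normalisation: Table-style labels (with optional parenthetical
## doubt, preserved as a note) or enum tokens. Returns NA for unknowns.
normalize_culture <- function(x) {
  x <- trimws(as.character(x))
  note <- rep(NA_character_, length(x))
  has_par <- grepl("\\([^()]*\\)$", x)
  note[has_par] <- gsub("^\\(|\\)$", "",
                        regmatches(x, regexpr("\\([^()]*\\)$", x)))
  base <- trimws(sub("\\([^()]*\\)$", "", x))
  key <- tolower(gsub("[ -]+", "_", base))
  map <- c(yamnaya = "yamnaya", pre_yamnaya = "pre_yamnaya",
           post_yamnaya = "post_yamnaya", corded_ware = "corded_ware",
           copper_age = "copper_age", middle_bronze_age = "middle_bronze_age",
           other = "other")
  list(culture = unname(map[key]), note = note)
}

#' Load the packaged 24-individual assemblage
#'
#' Loads the transcription of the published tables describing the 24
#' Early Bronze Age steppe individuals that display at least three of the
#' six diagnostic traits: the trait observation matrix (present / absent
#' / not preserved) joined with per-individual metadata (site, country,
#' skeletal completeness, sex, age range, cultural assignment,
#' radiocarbon information and the published score).
#'
#' The published scores embed an unpublished severity-of-expression
#' adjustment and are stored verbatim in \code{reported_score}, never
#' recomputed; compare them with \code{\link{base_score}} explicitly.
#'
#' @return An \code{\link{assemblage}} of 24 individuals.
#' @examples
#' fx <- load_fixture()
#' nrow(fx)            # 24
#' trait_count(fx)[["064"]]  # 6
#' @export
load_fixture <- function() {
  traits_path <- system.file("extdata", "table1_traits.tsv",
                             package = "ridescore", mustWork = TRUE)
  meta_path <- system.file("extdata", "table2_individuals.tsv",
                           package = "ridescore", mustWork = TRUE)
  traits <- utils::read.delim(traits_path, colClasses = "character",
                              check.names = FALSE, fileEncoding = "UTF-8")
  meta <- utils::read.delim(meta_path, colClasses = "character",
                            check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(sort(traits$individual_id), sort(meta$individual_id))) {
    stop("fixture corrupted: individual_id sets differ between the trait ",
         "and metadata files", call. = FALSE)
  }
  df <- merge(meta, traits, by = "individual_id", sort = FALSE)
  df <- df[order(df$individual_id), ]
  out <- assemblage(df, label = "published 24-individual assemblage",
                    provenance = "fixture")
  if (nrow(out) != 24L) {
    stop("fixture corrupted: expected 24 individuals, found ", nrow(out),
         call. = FALSE)
  }
  out
}

#' Read a trait observation table
#'
#' Reads a delimited text table (one row per skeleton) into an
#' \code{\link{assemblage}}. Trait state symbols \code{"+"},
#' \code{"-"} (ASCII hyphen), \code{"−"} (Unicode minus) and
#' \code{"?"} map to present / absent / absent / unobservable; the full
#' words are accepted too. Unrecognised symbols raise an error naming the
#' offending cell rather than being coerced.
#'
#' @param path Path to a UTF-8 delimited text file with one header row.
#'   Required columns: \code{individual_id}, \code{country},
#'   \code{site_label}, \code{completeness}, \code{sex}, \code{age_low},
#'   \code{age_high}, \code{culture} and the six canonical trait columns;
#'   optional: \code{culture_note}, \code{radiocarbon},
#'   \code{reported_score}.
#' @param sep Field separator. Default \code{NULL} infers from the file
#'   extension (\code{.csv} is comma-separated, anything else
#'   tab-separated).
#' @return An \code{\link{assemblage}}.
#' @seealso \code{\link{write_trait_table}}
#' @export
read_trait_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8", na.strings = NULL)
  missing <- setdiff(c(.required_cols, .trait_ids), names(df))
  if (length(missing) > 0L) {
    stop("trait table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("reported_score" %in% names(df)) {
    df$reported_score[df$reported_score == ""] <- NA
  }
  assemblage(df, label = basename(path), provenance = paste0("file:", path))
}

#' Write an assemblage as a delimited trait table
#'
#' Writes a table re-readable by \code{\link{read_trait_table}} with a
#' lossless state round-trip: present is written as \code{"+"}, absent as
#' the ASCII hyphen \code{"-"} and unobservable as \code{"?"}.
#'
#' @param x An \code{\link{assemblage}}.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return Invisibly, \code{path}.
#' @export
write_trait_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "assemblage"))
  df <- as.data.frame(x)
  for (tid in .trait_ids) df[[tid]] <- unname(.state_symbols_out[df[[tid]]])
  df$reported_score[is.na(df$reported_score)] <- ""
  df$culture_note[is.na(df$culture_note)] <- ""
  df$radiocarbon[is.na(df$radiocarbon)] <- ""
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
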