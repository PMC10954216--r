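#' @keywords internal
"_PACKAGE"

## Canonical trait order and state codes used throughout the package.
.trait_ids <- c("entheses", "ovalization", "lesion", "platymeric",
                "vertebral", "trauma")
.trait_weights <- c(3L, 3L, 2L, 2L, 1L, 1L)

.state_present <- "present"
.state_absent <- "absent"
.state_unobservable <- "unobservable"
.states <- c(.state_present, .state_absent, .state_unobservable)

## Symbol dialect for delimited trait tables. Unicode minus (U+2212) is
## accepted on input because published tables commonly use it; writers
## always emit the ASCII hyphen.
.state_symbols_in <- c("+" = "present", "-" = "absent", "−" = "absent",
                       "?" = "unobservable",
                       "present" = "present", "absent" = "absent",
                       "unobservable" = "unobservable")
.state_symbols_out <- c(present = "+", absent = "-", unobservable = "?")

.catalog_version <- "canonical-6trait-v1"

#' Canonical six-trait diagnostic catalog
#'
#' Returns the fixed catalog of six skeletal traits used to diagnose
#' habitual horseback riding ("horsemanship syndrome"), each with an
#' integer weight reflecting its relative diagnostic specificity. The
#' weights are (3, 3, 2, 2, 1, 1) and sum to 12, the maximum attainable
#' score.
#'
#' The traits, in canonical order:
#' \enumerate{
#'   \item \code{entheses} (3): pronounced entheseal stress reactions at
#'     the attachment sites of the hip adductor and gluteal muscles on
#'     pelvis and femur, from continual gripping of a mount.
#'   \item \code{ovalization} (3): anterosuperior extension and
#'     thickening of the acetabular rim, a response to pressure from the
#'     femoral neck in a seated posture with drawn-up legs.
#'   \item \code{lesion} (2): femoroacetabular impression dent with a
#'     dense raised margin on the anterosuperior femoral neck from
#'     repeated hip contact.
#'   \item \code{platymeric} (2): anteroposterior flattening of the
#'     proximal femoral shaft (platymeric index below 85) with thickened
#'     medial/lateral cortex, an adaptation to mediolateral bending
#'     stress.
#'   \item \code{vertebral} (1): symmetric degeneration of the lower
#'     thoracic and lumbar spine with concave end plates and Schmorl's
#'     nodes from repetitive vertical compression.
#'   \item \code{trauma} (1): healed traumatic lesions consistent with a
#'     fall from height, such as a displaced sacral spinous process.
#' }
#'
#' @return A data frame with columns \code{trait_id}, \code{name},
#'   \code{weight} (integer) and \code{description}, one row per trait in
#'   canonical order.
#' @examples
#' cat <- trait_catalog()
#' sum(cat$weight)  # 12
#' @export
trait_catalog <- function() {
  data.frame(
    trait_id = .trait_ids,
    name = c("Femoral/pelvic entheses",
             "Ovalization of acetabulum",
             "Femoroacetabular lesion",
             "Platymeric femur",
             "Specific vertebral degeneration",
             "Specific trauma"),
    weight = .trait_weights,
    description = c(
      "Pronounced entheseal stress reactions at hip adductor and gluteal muscle attachments on pelvis and femur",
      "Anterosuperior extension and thickening of the acetabular rim from femoroacetabular pressure in a drawn-up-leg seat",
      "Impression dent with raised dense margin on the anterosuperior femoral neck from repeated hip contact",
      "Anteroposterior flattening of the subtrochanteric femoral shaft (platymeric index < 85) with thickened medial/lateral cortex",
      "Symmetric lower thoracic/lumbar degeneration with concave end plates and Schmorl's nodes from vertical compression stress",
      "Healed trauma consistent with falls from height, e.g. displaced sacral spinous process"),
    stringsAsFactors = FALSE
  )
}

## Weight lookup in catalog order, validated against a user-supplied catalog.
.catalog_weights <- function(catalog = trait_catalog()) {
  if (!is.data.frame(catalog) ||
      !all(c("trait_id", "weight") %in% names(catalog))) {
    stop("catalog must be a data frame with columns 'trait_id' and 'weight'",
         call. = FALSE)
  }
  missing <- setdiff(.trait_ids, catalog$trait_id)
  if (length(missing) > 0L) {
    stop("catalog is missing trait(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- catalog$weight[match(.trait_ids, catalog$trait_id)]
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("catalog weights must be non-negative numbers", call. = FALSE)
  }
  as.integer(w)
}
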