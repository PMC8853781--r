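#' Field types of a TCM electronic medical record
#'
#' Every record carries up to seven free-text diagnostic fields plus a
#' syndrome label.  The seven diagnostic fields are the four-diagnosis
#' information (tongue inspection, pulse taking, listening and smelling,
#' inspection) together with body surface examination, diagnosis of TCM and
#' nursing precautions.  `field_types()` returns the seven diagnostic field
#' identifiers; `entity_types()` appends `"syndrome"`, giving the eight
#' entity categories of the knowledge graph.
#'
#' Nursing precautions are kept in the graph for richness but are never used
#' as evidence when recommending a diagnosis; see [dismantle_record()].
#'
#' @return Character vector of field identifiers (snake_case).
#' @export
#' @examples
#' field_types()
#' entity_types()
field_types <- function() {
  c("tongue_inspection", "pulse_taking", "listening_and_smelling",
    "inspection", "body_surface_examination", "diagnosis_of_tcm",
    "nursing_precautions")
}

#' @rdname field_types
#' @export
entity_types <- function() c(field_types(), "syndrome")

#' @rdname field_types
#' @export
diagnostic_field_types <- function() setdiff(field_types(), "nursing_precautions")

# Human-readable labels, used in reports only.
field_labels <- c(
  tongue_inspection        = "tongue inspection",
  pulse_taking             = "pulse taking",
  listening_and_smelling   = "listening and smelling",
  inspection               = "inspection",
  body_surface_examination = "body surface examination",
  diagnosis_of_tcm         = "diagnosis of TCM",
  nursing_precautions      = "nursing precautions",
  syndrome                 = "syndrome"
)

#' Default punctuation set for field segmentation
#'
#' ASCII and full-width (CJK) separators used to split a raw field text into
#' symptom tokens.  The clinical texts this package targets delimit findings
#' with mixed half-width/full-width commas, semicolons, the ideographic full
#' stop and the enumeration comma; the exact set is configurable in every
#' operation that segments text.
#'
#' @return Character vector of single separator characters.
#' @export
default_punctuation <- function() {
  c(",", ";", "。", "，", "、", "；", "　")
}
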