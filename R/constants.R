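#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across the pipeline.
## Marks: the CUT&Tag antibody panel (TF = c-Fos; IgG = negative control).
MARK_LEVELS <- c("TF", "H3K27ac", "H3K4me3", "H3K27me3", "IgG")
GROUP_LEVELS <- c("normal", "OIR")
TIMEPOINT_LEVELS <- c("P14", "P17")

#' Controlled vocabularies used by the pipeline
#'
#' Mark labels name the CUT&Tag antibody panel: the transcription factor
#' itself (`"TF"`, c-Fos in the default workflow), the active-enhancer mark
#' H3K27ac, the active-promoter mark H3K4me3, the repressive mark H3K27me3,
#' and the IgG control. Conditions are `group` (normal vs OIR, the
#' oxygen-induced retinopathy model) crossed with `timepoint` (P14, P17).
#'
#' @return A named list with character vectors `marks`, `groups`,
#'   `timepoints`.
#' @export
#' @examples
#' pipeline_vocab()$marks
pipeline_vocab <- function() {
  list(marks = MARK_LEVELS, groups = GROUP_LEVELS, timepoints = TIMEPOINT_LEVELS)
}
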