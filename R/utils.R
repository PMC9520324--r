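#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows bind_cols across n row_number rename pull distinct
#' @importFrom stats predict rnorm runif sd t.test oneway.test cor qnorm dnorm
#' @importFrom utils head tail
NULL

# Modality layout used everywhere: four blocks of monitoring indices.
MODALITIES <- list(
  PW = paste0("PW-", 1:6),
  TL = paste0("TL-", 1:2),
  PR = paste0("PR-", 1:6),
  PP = paste0("PP-", 1:4)
)

FEATURE_NAMES <- unname(unlist(MODALITIES))

FEATURE_LABELS <- c(
  "PW-1" = "Menses", "PW-2" = "Fatigue (EWMA)", "PW-3" = "Sleep (EWMA)",
  "PW-4" = "MS (EWMA)", "PW-5" = "Stress (EWMA)", "PW-6" = "Desire (EWMA)",
  "TL-1" = "TM (sRPE)", "TL-2" = "sRPE (EWMA)",
  "PR-1" = "Urine Protein", "PR-2" = "Urobilinogen", "PR-3" = "Urine pH",
  "PR-4" = "Urine Specific Gravity", "PR-5" = "Urine Blood",
  "PR-6" = "Urine Ketones",
  "PP-1" = "Squat 1RM", "PP-2" = "5.8 m x 6 Shuttle Run",
  "PP-3" = "15 m x 17 Shuttle Run", "PP-4" = "MVJ"
)

# Admissible codes for the weekly urinalysis panel.
URINE_CODES <- list(
  protein          = 1:5,
  urobilinogen     = c(1, 5, 10),
  ph               = 5:8,
  specific_gravity = 1:2,
  blood            = c(1, 2, 3, 4, 6),
  ketones          = 1:3
)

LE_SITES <- c("hip", "knee", "thigh", "calf", "ankle", "foot")

feature_modality <- function(feature) {
  sub("-.*$", "", feature)
}

# Population (divisor n) standard deviation; the windowed statistics and the
# per-athlete normalisation both use it.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- rlang::`%||%`
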