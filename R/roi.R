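#' Default 14-region pain/default-mode parcellation
#'
#' The region-of-interest (ROI) set used throughout the package: ten
#' pain-network parcels (bilateral Brodmann areas 1, 2, 3, 13 and 32) and
#' four default-mode-network (DMN) parcels (medial prefrontal cortex,
#' posterior cingulate cortex, and the left and right lateral parietal
#' cortices). Each averaged BOLD signal of a parcel forms one network node.
#'
#' @return A tibble with one row per ROI and columns `label`, `network`
#'   (`"pain"` or `"DMN"`) and `hemisphere` (`"L"`, `"R"` or `"midline"`).
#' @examples
#' default_roi_set()
#' @export
default_roi_set <- function() {
  tibble::tibble(
    label = c(
      "BA1_L", "BA1_R", "BA2_L", "BA2_R", "BA3_L", "BA3_R",
      "BA13_L", "BA13_R", "BA32_L", "BA32_R",
      "mPFC", "PCC", "LateralParietal_L", "LateralParietal_R"
    ),
    network = c(rep("pain", 10), rep("DMN", 4)),
    hemisphere = c(
      rep(c("L", "R"), 5),
      "midline", "midline", "L", "R"
    )
  )
}

#' Validate an ROI set table
#'
#' @param roi_set A data frame with columns `label`, `network`, `hemisphere`.
#' @return The validated ROI set as a tibble (invisibly usable in pipes).
#' @keywords internal
validate_roi_set <- function(roi_set) {
  roi_set <- tibble::as_tibble(roi_set)
  required <- c("label", "network", "hemisphere")
  missing <- setdiff(required, names(roi_set))
  if (length(missing) > 0) {
    abort(paste0("ROI set is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(roi_set$label)) {
    abort("ROI labels must be unique.")
  }
  bad <- setdiff(unique(roi_set$network), c("pain", "DMN"))
  if (length(bad) > 0) {
    abort(paste0("Unknown network membership: ", paste(bad, collapse = ", ")))
  }
  roi_set
}

#' Read an ROI set from a CSV file
#'
#' Expects columns `label`, `network` (pain|DMN) and `hemisphere` (L|R|midline).
#'
#' @param path Path to a CSV file.
#' @return A validated ROI tibble.
#' @export
read_roi_set <- function(path) {
  validate_roi_set(readr::read_csv(path, show_col_types = FALSE))
}
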