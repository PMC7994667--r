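#' Validate a sample-design table
#'
#' A sample design describes one column of an expression matrix per row:
#' which cell line it came from, which treatment (`SL` for serum/LIF, `2i`,
#' or `Cdk8i`), the timepoint (hours or days, non-negative), the isobaric
#' plex (batch label) and the replicate index. Every non-reference sample
#' must have a serum/LIF reference channel in the same plex, because all
#' downstream ratios are formed against the within-plex reference.
#'
#' @param design data.frame with columns `sample_id`, `cell_line`,
#'   `treatment`, `timepoint`, `plex`, `replicate`.
#' @param require_reference logical; check the same-plex reference rule
#'   (disable for label-free layers such as the metabolome).
#' @return the design, invisibly, with `treatment` as character.
#' @export
validate_design <- function(design, require_reference = TRUE) {
  required <- c("sample_id", "cell_line", "treatment", "timepoint",
                "plex", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  design$treatment <- as.character(design$treatment)
  bad <- setdiff(unique(design$treatment), TREATMENTS)
  if (length(bad) > 0) {
    stop("unknown treatment token(s): ", paste(bad, collapse = ", "),
         "; allowed values are: ", paste(TREATMENTS, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  }
  if (any(design$timepoint < 0)) stop("timepoints must be non-negative")
  if (any(design$replicate < 1)) stop("replicate indices must be >= 1")
  if (require_reference) {
    for (px in unique(design$plex)) {
      rows <- design[design$plex == px, ]
      if (any(rows$treatment != "SL") && !any(rows$treatment == "SL")) {
        stop("plex '", px, "' has treated samples but no SL reference channel")
      }
    }
  }
  invisible(design)
}

#' Read a sample-design table from TSV/CSV
#'
#' @param path file with header columns `sample_id`, `cell_line`,
#'   `treatment`, `timepoint`, `plex`, `replicate`.
#' @param require_reference passed to [validate_design()].
#' @return validated design data.frame.
#' @export
read_design <- function(path, require_reference = TRUE) {
  design <- read_delim_auto(path)
  validate_design(design, require_reference = require_reference)
  design$treatment <- as.character(design$treatment)
  design$sample_id <- as.character(design$sample_id)
  design$plex <- as.character(design$plex)
  design
}
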