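#' Region-of-interest set
#'
#' A `roi_set` describes the network nodes of the region-level analysis: an
#' ordered list of region labels and a cortical/subcortical class for each.
#' The default set holds the 20 regions used throughout the package, 10
#' subcortical (thalamic nuclei groups, hippocampus, striatum, hypothalamus,
#' pallidum, basal forebrain, reticular thalamic nucleus, ventral tegmental
#' area) followed by 10 cortical areas.
#'
#' @param names character vector of unique region labels.
#' @param class character vector, same length, each `"cortical"` or
#'   `"subcortical"`.
#' @return An object of class `roi_set`: a list with elements `names`,
#'   `class`, `n`.
#' @export
roi_set <- function(names, class) {
  stopifnot(is.character(names), length(names) == length(class))
  if (anyDuplicated(names)) stop("ROI labels must be unique")
  if (!all(class %in% c("cortical", "subcortical"))) {
    stop("ROI class must be 'cortical' or 'subcortical'")
  }
  structure(list(names = names, class = stats::setNames(class, names),
                 n = length(names)),
            class = "roi_set")
}

#' Default 20-region rat ROI set
#'
#' 10 subcortical then 10 cortical regions; the balanced split is relied on by
#' the block-structured simulator and the block-scoped similarity analysis.
#'
#' @return A `roi_set` with 20 regions.
#' @export
default_roi_set <- function() {
  sub <- c("Thal-HO", "Thal-EPI", "Thal-NS", "Hippo", "Stria",
           "Hypo", "Pal", "BF", "TRN", "VTA")
  ctx <- c("Ccx", "RSP", "PPC", "TC", "OC", "SS", "VC", "MC",
           "Insular", "PrL")
  roi_set(c(sub, ctx), c(rep("subcortical", 10), rep("cortical", 10)))
}

#' Indices of regions of one class
#'
#' @param rois a `roi_set`.
#' @param class `"cortical"` or `"subcortical"`.
#' @return Integer vector of positions in `rois$names`.
#' @export
roi_indices <- function(rois, class) {
  which(unname(rois$class) == class)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d regions (%d cortical, %d subcortical)\n",
              x$n, sum(x$class == "cortical"), sum(x$class == "subcortical")))
  invisible(x)
}
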