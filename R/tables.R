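# Published BreakHis reference tables shipped as plain-text inputs: the
# benchmark's per-subtype image counts and the reported per-class metric and
# cross-validation cells. These drive the counting/balancing arithmetic and
# the worked-example metric recomputations without the image data.

ref_table <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "gwovit",
                              mustWork = TRUE))
}

#' BreakHis per-subtype image counts
#'
#' The benchmark's published image counts by class, subtype and
#' magnification (columns `X40`..`X400`).
#'
#' @return data.frame of counts.
#' @export
breakhis_counts <- function() ref_table("breakhis_counts.csv")

#' Published class-wise precision/recall cells
#'
#' @param model `"baseline"` or `"gwo"`.
#' @return data.frame (magnification, class, precision, recall).
#' @export
breakhis_classwise_metrics <- function(model = c("baseline", "gwo")) {
  model <- match.arg(model)
  df <- ref_table("breakhis_classwise_metrics.csv")
  df[df$model == model, -1]
}

#' Published 5-fold cross-validation accuracy cells
#'
#' `"by_mag"` returns the per-magnification fold accuracies; `"40x_detail"`
#' the full 40X table (train/val/test accuracy, precision, F1 per fold).
#'
#' @param which table selector.
#' @return data.frame.
#' @export
breakhis_cv_folds <- function(which = c("by_mag", "40x_detail")) {
  which <- match.arg(which)
  ref_table(paste0("breakhis_cv_", which, ".csv"))
}
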