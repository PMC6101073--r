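#' Majority-based cluster-to-type matching
#'
#' Labels every predicted cluster with the most frequent ground-truth class
#' among its cells (several clusters may map to the same class, so methods
#' that split a true type into pure sub-clusters are not penalized). Ties
#' are broken toward the class with fewer cells overall, then
#' lexicographically.
#'
#' @param assignment a `ClusterAssignment`.
#' @param truth named vector mapping every cell id to its class.
#' @return Named character vector: cluster id -> class label.
#' @export
majority_match <- function(assignment, truth) {
  lab <- assignment$labels
  cells <- names(lab)
  if (is.null(cells)) stop_value("assignment has no cell ids")
  missing <- setdiff(cells, names(truth))
  if (length(missing))
    stop_value("cell missing from truth: ", missing[1])
  tr <- as.character(truth[cells])
  class_sizes <- table(tr)
  out <- vapply(sort(unique(lab)), function(cl) {
    tab <- table(tr[lab == cl])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      sz <- class_sizes[top]
      top <- top[sz == min(sz)]
      top <- sort(top)[1]
    }
    top
  }, "")
  stats::setNames(out, sort(unique(lab)))
}

#' Clustering accuracy against ground truth
#'
#' Computes the majority matching, then per-class accuracy C_i / N_i (C_i =
#' cells of class i inside clusters matched to class i, N_i = class size),
#' micro accuracy sum(C_i) / sum(N_i) (equal weight per cell) and macro
#' accuracy mean(C_i / N_i) over the K truth classes (equal weight per
#' class). For balanced 1:1 mixtures macro and micro coincide.
#'
#' @inheritParams majority_match
#' @return An `AccuracyReport`: list with `per_class_accuracy`, `macro`,
#'   `micro`, `matching`, `confusion` (cluster x class counts), `n_classes`.
#' @examples
#' a <- sctfidf:::new_cluster_assignment(
#'   stats::setNames(c(0, 0, 1, 1), paste0("c", 1:4)), "demo")
#' accuracy(a, stats::setNames(c("A", "A", "B", "B"), paste0("c", 1:4)))$macro
#' @export
accuracy <- function(assignment, truth) {
  matching <- majority_match(assignment, truth)
  lab <- assignment$labels
  tr <- as.character(truth[names(lab)])
  classes <- if (is.factor(truth)) levels(truth)
             else sort(unique(as.character(truth)))
  present <- classes[classes %in% tr]
  if (length(present) < length(classes))
    warning("truth class(es) with zero cells excluded from K: ",
            paste(setdiff(classes, present), collapse = ", "))
  classes <- present
  conf <- table(cluster = lab, class = factor(tr, levels = classes))
  predicted <- matching[as.character(lab)]
  N <- vapply(classes, function(cl) sum(tr == cl), 0)
  C <- vapply(classes, function(cl) sum(tr == cl & predicted == cl), 0)
  per_class <- C / N
  structure(list(per_class_accuracy = per_class,
                 macro = mean(per_class),
                 micro = sum(C) / sum(N),
                 matching = matching,
                 confusion = conf,
                 n_classes = length(classes)),
            class = "AccuracyReport")
}

#' @export
print.AccuracyReport <- function(x, ...) {
  cat(sprintf("AccuracyReport: macro %.4f, micro %.4f over %d classes\n",
              x$macro, x$micro, x$n_classes))
  print(round(x$per_class_accuracy, 4))
  invisible(x)
}
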