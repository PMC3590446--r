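#' Full detection pipeline
#'
#' Orchestrates the three detection stages on one volume: builds the
#' candidate search space (from a supplied mask, or the gray-threshold
#' stand-in), runs the GA template search once per template shape, merges
#' the per-shape harvests by non-maximum suppression, locally refines
#' each surviving candidate's radius and center ([refine_candidates()]),
#' extracts the three nodule features, and classifies candidates as TPN
#' or FPN (training a
#' classifier first if a training set rather than a model is supplied).
#' When ground truth is supplied the report scores detections with a
#' center-distance matching radius of `max(3, R/2)` voxels.  Deterministic
#' per `config$seed`: per-shape GA runs use `seed + shape index`.
#'
#' @param vol a [nod_volume()].
#' @param mask optional binary [nod_volume()] of candidate tissue.
#' @param q_low gray threshold used when no mask is given.
#' @param shapes template shapes to run.
#' @param config a [ga_config()].
#' @param model a trained `lcg_model`, or `NULL` to train from `training`.
#' @param training labeled feature data frame (see
#'   [make_feature_training_set()]), used when `model` is `NULL`.
#' @param truth optional ground-truth nodule data frame (columns `x`,
#'   `y`, `z`, `R`).
#' @param min_component connected-component filter for the search space.
#' @param match_radius function of the true radius giving the matching
#'   distance in voxels.
#' @return list of class `detection_result` with elements `candidates`
#'   (final candidate table) and `report` (a `detection_report`).
#' @export
run_pipeline <- function(vol, mask = NULL, q_low = NULL,
                         shapes = c("circle", "semicircle", "sphere",
                                    "hollow_sphere"),
                         config = ga_config(), model = NULL,
                         training = NULL, truth = NULL,
                         min_component = 1,
                         match_radius = function(R) pmax(3, R / 2)) {
  if (is.null(mask) && is.null(q_low))
    stop("pipeline needs either a candidate mask or a threshold q_low")
  space <- if (is.null(mask)) space_from_threshold(vol, q_low, min_component)
           else space_from_mask(mask, min_component)
  if (nrow(space$voxels) == 0)
    stop("pipeline stage 'candidate_space': search space is empty")
  # features are measured on the candidate-space mask (the segmented
  # object), which is component-filtered and hole-filled
  feat_mask <- space_to_mask(space, dim(vol$data))

  per_shape <- list()
  for (si in seq_along(shapes)) {
    cfg <- config
    cfg$seed <- config$seed + si
    per_shape[[shapes[si]]] <- tryCatch(
      ga_search(vol, space, shapes[si], cfg),
      error = function(e) stop("pipeline stage 'matching' (", shapes[si],
                               "): ", conditionMessage(e)))
  }
  pre_counts <- vapply(per_shape, nrow, integer(1))
  merged <- nms_candidates(do.call(rbind, per_shape))
  # pin radius and center at each surviving location before measuring
  # features on the template support
  merged <- refine_candidates(vol, merged, config)
  merged <- nms_candidates(merged)
  rownames(merged) <- NULL

  classified <- merged
  if (nrow(merged)) {
    if (is.null(model)) {
      if (is.null(training)) training <- make_feature_training_set(
        seed = config$seed)
      model <- train_classifier(training, seed = config$seed)
    }
    classified <- tryCatch({
      feats <- extract_features(vol, feat_mask, merged, config)
      classify_candidates(feats, model)
    }, error = function(e) stop("pipeline stage 'fpn_classifier': ",
                                conditionMessage(e)))
  }
  accepted <- classified[!is.na(classified$label) &
                           classified$label == "TPN", , drop = FALSE]

  report <- list(seed = config$seed, shapes = shapes,
                 pre_classification = pre_counts,
                 merged_candidates = nrow(merged),
                 post_classification = nrow(accepted),
                 config = config)
  if (!is.null(truth)) {
    sc <- score_detections(accepted, truth, match_radius)
    report <- c(report, sc)
  }
  class(report) <- "detection_report"
  structure(list(candidates = classified, report = report),
            class = "detection_result")
}

# Greedy matching of accepted candidates to ground truth by center
# distance; each candidate matches at most one truth nodule.
score_detections <- function(accepted, truth, match_radius) {
  used <- rep(FALSE, nrow(accepted))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    rad <- match_radius(truth$R[i])
    if (nrow(accepted)) {
      d <- sqrt((accepted$x - truth$x[i])^2 + (accepted$y - truth$y[i])^2 +
                  (accepted$z - truth$z[i])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= rad) {
        tp <- tp + 1L
        used[j] <- TRUE
      }
    }
  }
  list(TP = tp, FN = nrow(truth) - tp, FP = sum(!used),
       n_truth = nrow(truth))
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report (seed", x$seed, ")\n")
  cat("  candidates per shape before NMS/classification:\n")
  for (s in names(x$pre_classification))
    cat(sprintf("    %-14s %d\n", s, x$pre_classification[[s]]))
  cat("  merged candidates:", x$merged_candidates, "\n")
  cat("  accepted after classification:", x$post_classification, "\n")
  if (!is.null(x$TP))
    cat(sprintf("  vs truth: TP %d, FP %d, FN %d (of %d planted)\n",
                x$TP, x$FP, x$FN, x$n_truth))
  invisible(x)
}
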