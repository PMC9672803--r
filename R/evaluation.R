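#' Evaluation configuration
#'
#' Parameters of the lesion-level evaluation: connected-component
#' connectivity, the minimum lesion volume (lesions strictly smaller than
#' `min_lesion_mm3` are removed from both prediction and ground truth
#' before matching), and the detection-matching parameters `alpha`, `beta`,
#' `gamma`.
#'
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_lesion_mm3 minimum lesion volume in mm^3 (default 3).
#' @param alpha minimum fraction of a target lesion that must be covered
#'   (default 0.10).
#' @param beta bounds how much of a matched component may lie outside the
#'   other segmentation (default 0.65).
#' @param gamma bounds the total volume inflation of the matched components
#'   (default 0.70).
#' @return an object of class `eval_config`.
#' @export
eval_config <- function(connectivity = 26L, min_lesion_mm3 = 3,
                        alpha = 0.10, beta = 0.65, gamma = 0.70) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("eval_config: connectivity must be 6, 18 or 26")
  for (v in c(alpha, beta, gamma))
    if (v <= 0 || v > 1) stopf("eval_config: alpha/beta/gamma must be in (0, 1]")
  structure(list(connectivity = as.integer(connectivity),
                 min_lesion_mm3 = as.double(min_lesion_mm3),
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "eval_config")
}

mask_array <- function(m) {
  a <- if (inherits(m, "volume3d")) m$data else m
  vals <- unique(as.vector(a))
  if (!all(vals %in% c(0, 1)))
    stopf("expected a binary mask, found values %s",
          paste(utils::head(sort(vals), 5), collapse = ", "))
  a
}

#' Individualize lesions by connected components
#'
#' @param mask binary [volume3d()] (or array, assumed 1 mm voxels).
#' @param cfg an [eval_config()].
#' @return an object of class `lesion_labeling`: `labels` (integer array,
#'   0 = background, k = lesion k with consecutive labels 1..K), `table`
#'   (data.frame with `label`, `voxels`, `volume_mm3`), `voxel_size_mm`.
#' @export
label_lesions <- function(mask, cfg = eval_config()) {
  vs <- if (inherits(mask, "volume3d")) mask$voxel_size_mm else rep(1, 3)
  a <- mask_array(mask)
  lab <- label_components_cpp(as.integer(a), as.integer(dim(a)),
                              cfg$connectivity)
  K <- max(lab)
  voxels <- if (K > 0) tabulate(lab[lab > 0L], nbins = K) else integer(0)
  structure(list(labels = lab,
                 table = data.frame(label = seq_len(K), voxels = voxels,
                                    volume_mm3 = voxels * prod(vs)),
                 voxel_size_mm = vs),
            class = "lesion_labeling")
}

#' @export
print.lesion_labeling <- function(x, ...) {
  cat(sprintf("<lesion_labeling> %d lesions, %d voxels total\n",
              nrow(x$table), sum(x$table$voxels)))
  invisible(x)
}

#' Remove lesions below the minimum volume
#'
#' Removes every lesion whose volume is strictly smaller than
#' `cfg$min_lesion_mm3` ("smaller than" is a strict inequality: a lesion of
#' exactly the minimum volume survives) and relabels the survivors
#' consecutively.
#'
#' @param labeling a [label_lesions()] result.
#' @param cfg an [eval_config()].
#' @return a filtered `lesion_labeling`.
#' @export
filter_small <- function(labeling, cfg = eval_config()) {
  stopifnot(inherits(labeling, "lesion_labeling"))
  keep <- labeling$table$label[labeling$table$volume_mm3 >= cfg$min_lesion_mm3]
  remap <- integer(nrow(labeling$table) + 1L)  # index 1 = background 0
  remap[keep + 1L] <- seq_along(keep)
  lab <- labeling$labels
  lab[] <- remap[lab + 1L]
  tb <- labeling$table[labeling$table$label %in% keep, , drop = FALSE]
  tb$label <- seq_along(keep)
  rownames(tb) <- NULL
  structure(list(labels = lab, table = tb,
                 voxel_size_mm = labeling$voxel_size_mm),
            class = "lesion_labeling")
}

# Default detection rule. A target lesion g (of labeling A) is detected by
# labeling B iff
#   (i)   at least alpha of g is covered by B,
#   (ii)  every B-component overlapping g has at least (1 - beta) of its own
#         volume inside A (it is not mostly a spurious blob), and
#   (iii) the total volume of the components overlapping g does not exceed
#         |g| / (1 - gamma) (bounded volume inflation).
# The rule is applied symmetrically to define TP_gt and TP_pred.
default_detection_rule <- function(a_lab, b_lab, cfg) {
  Ka <- nrow(a_lab$table)
  if (Ka == 0L) return(logical(0))
  a <- a_lab$labels; b <- b_lab$labels
  Kb <- nrow(b_lab$table)
  a_sizes <- a_lab$table$voxels
  b_sizes <- b_lab$table$voxels
  detected <- logical(Ka)
  if (Kb == 0L) return(detected)
  both <- which(a > 0L & b > 0L)
  if (length(both) == 0L) return(detected)
  ov <- table(factor(a[both], levels = seq_len(Ka)),
              factor(b[both], levels = seq_len(Kb)))
  ov <- matrix(as.integer(ov), Ka, Kb)
  # fraction of each b-component inside the whole of A
  b_in_a <- tabulate(b[which(b > 0L & a > 0L)], nbins = Kb) / b_sizes
  for (g in seq_len(Ka)) {
    covered <- sum(ov[g, ]) / a_sizes[g]
    if (covered < cfg$alpha) next
    comps <- which(ov[g, ] > 0L)
    if (any(b_in_a[comps] < 1 - cfg$beta)) next
    if (sum(b_sizes[comps]) > a_sizes[g] / (1 - cfg$gamma)) next
    detected[g] <- TRUE
  }
  detected
}

#' Lesion-level detection matching
#'
#' Matches predicted and ground-truth lesions with the parameterized
#' overlap rule (`alpha` = minimum covered fraction of the target lesion,
#' `beta` = how much of a matched component may lie outside the other
#' segmentation, `gamma` = bound on total matched-volume inflation),
#' applied symmetrically: `TP_gt` counts ground-truth lesions detected by
#' the prediction, `TP_pred` counts predicted lesions confirmed by the
#' ground truth. The rule is pluggable via `rule` so an alternative
#' matching algorithm can be swapped in; the default is a documented
#' interpretation, not a verbatim reproduction of any published matcher.
#'
#' @param pred,gt [label_lesions()] results on the same grid.
#' @param cfg an [eval_config()].
#' @param rule function `(target_labeling, other_labeling, cfg)` returning
#'   a logical detection flag per target lesion.
#' @return an object of class `lesion_matching` with `TP_gt`, `TP_pred`,
#'   `n_gt`, `n_pred`, `gt_detected`, `pred_detected`.
#' @export
match_lesions <- function(pred, gt, cfg = eval_config(),
                          rule = default_detection_rule) {
  stopifnot(inherits(pred, "lesion_labeling"), inherits(gt, "lesion_labeling"))
  if (!identical(dim(pred$labels), dim(gt$labels)))
    stopf("match_lesions: grid mismatch (%s) vs (%s)",
          paste(dim(pred$labels), collapse = ","),
          paste(dim(gt$labels), collapse = ","))
  gt_det <- rule(gt, pred, cfg)
  pred_det <- rule(pred, gt, cfg)
  structure(list(TP_gt = sum(gt_det), TP_pred = sum(pred_det),
                 n_gt = nrow(gt$table), n_pred = nrow(pred$table),
                 gt_detected = gt_det, pred_detected = pred_det),
            class = "lesion_matching")
}

#' Voxel-level Dice score
#'
#' `2 |PRED intersect GT| / (|PRED| + |GT|)`. By convention the score is 1
#' when both masks are empty and 0 when exactly one is empty.
#'
#' @param pred_mask,gt_mask binary masks ([volume3d()] or array) on the
#'   same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred_mask, gt_mask) {
  p <- mask_array(pred_mask); g <- mask_array(gt_mask)
  if (!identical(dim(p), dim(g))) stopf("dice: grid mismatch")
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(1)
  2 * sum(p * g) / (sp + sg)
}

#' Per-patient metrics
#'
#' Lesion-level sensitivity `Sens = TP_gt / n_gt`, positive predictive
#' value `PPV = TP_pred / n_pred`, their harmonic mean
#' `F1 = 2 Sens PPV / (Sens + PPV)` (0 when `Sens + PPV = 0`), the
#' voxel-level Dice, plus the predicted lesion count and volume used for
#' the no-new-lesion subset. Patients with an empty (filtered) ground truth
#' have undefined Sens/PPV/F1/Dice entries (`NA`) and are routed to the
#' "without new lesions" subset by [cohort_summary()].
#'
#' @param matching a [match_lesions()] result.
#' @param pred_mask,gt_mask the binary masks after filtering.
#' @param pred_labeling the filtered prediction labeling (for lesion count
#'   and volume bookkeeping).
#' @param patient_id optional id string.
#' @return an object of class `patient_metrics` (one-row data.frame).
#' @export
patient_metrics <- function(matching, pred_mask, gt_mask, pred_labeling,
                            patient_id = NA_character_) {
  stopifnot(inherits(matching, "lesion_matching"))
  has_new <- matching$n_gt > 0L
  sens <- if (has_new) matching$TP_gt / matching$n_gt else NA_real_
  ppv <- if (matching$n_pred > 0L) matching$TP_pred / matching$n_pred
         else if (has_new) 0 else NA_real_
  f1 <- if (!has_new) NA_real_
        else if (is.na(ppv) || sens + ppv == 0) 0
        else 2 * sens * ppv / (sens + ppv)
  out <- data.frame(patient_id = patient_id,
                    has_new_lesions = has_new,
                    dice = if (has_new) dice(pred_mask, gt_mask) else NA_real_,
                    sens = sens, ppv = if (has_new) ppv else NA_real_,
                    f1 = f1,
                    n_pred_lesions = matching$n_pred,
                    pred_volume_mm3 = sum(pred_labeling$table$volume_mm3))
  class(out) <- c("patient_metrics", class(out))
  out
}

#' Evaluate one prediction/ground-truth pair
#'
#' Full lesion-level pipeline for a single patient: label both masks,
#' filter lesions below the minimum volume from both, match, and compute
#' the per-patient metrics.
#'
#' @param pred_mask,gt_mask binary masks on the same grid.
#' @param cfg an [eval_config()].
#' @param patient_id optional id string.
#' @return a [patient_metrics()] row.
#' @export
evaluate_case <- function(pred_mask, gt_mask, cfg = eval_config(),
                          patient_id = NA_character_) {
  pl <- filter_small(label_lesions(pred_mask, cfg), cfg)
  gl <- filter_small(label_lesions(gt_mask, cfg), cfg)
  pm <- (pl$labels > 0L) * 1
  gm <- (gl$labels > 0L) * 1
  m <- match_lesions(pl, gl, cfg)
  patient_metrics(m, pm, gm, pl, patient_id)
}

#' Cohort summary: mean and SEM per metric, split by subset
#'
#' Patients with new lesions contribute Dice/Sens/PPV/F1; patients without
#' new lesions contribute the predicted lesion count and predicted lesion
#' volume (for them any prediction is a false positive). SEM is the sample
#' SD (n - 1 denominator) divided by `sqrt(n)`; with a single patient the
#' SEM is reported as `NA`.
#'
#' @param per_patient a data.frame of [patient_metrics()] rows (row-bound).
#' @return list with `with_lesions` and `without_lesions`, each a
#'   data.frame with columns `metric`, `mean`, `sem`, `n`.
#' @export
cohort_summary <- function(per_patient) {
  if (NROW(per_patient) == 0L) stopf("cohort_summary: empty input")
  summarize <- function(df, metrics) {
    rows <- lapply(metrics, function(mname) {
      v <- df[[mname]]
      v <- v[!is.na(v)]
      n <- length(v)
      data.frame(metric = mname,
                 mean = if (n > 0) mean(v) else NA_real_,
                 sem = if (n > 1) sd(v) / sqrt(n) else NA_real_,
                 n = n)
    })
    do.call(rbind, rows)
  }
  with_l <- per_patient[per_patient$has_new_lesions, , drop = FALSE]
  wo_l <- per_patient[!per_patient$has_new_lesions, , drop = FALSE]
  list(with_lesions = summarize(with_l, c("dice", "sens", "ppv", "f1")),
       without_lesions = summarize(wo_l, c("n_pred_lesions",
                                           "pred_volume_mm3")))
}
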