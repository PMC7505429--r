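## Evaluation suite: pixel-overlap statistics (sensitivity, specificity,
## accuracy, precision/recall/F1), boundary localization error (BLE) on
## radial contours, and a ROC-AUC utility.

#' Contingency table of a segmentation against ground truth
#'
#' Binarizes 3-class label masks for an evaluation region and counts
#' TP/TN/FP/FN. Region `"OD"` treats labels \{1, 2\} as foreground (the
#' anatomical disc contains the cup); `"OD_rim"` uses label 1 only; `"OC"`
#' uses label 2; an integer `0..2` gives one-vs-rest for that class.
#'
#' @param pred,truth equal-shaped label masks with values in 0..2.
#' @param region `"OD"`, `"OC"`, `"OD_rim"`, or a class integer.
#' @return list of class `contingency` with TP, TN, FP, FN, P, N.
#' @export
contingency <- function(pred, truth, region = "OD") {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  bin <- function(m) {
    if (identical(region, "OD")) m == 1 | m == 2
    else if (identical(region, "OC")) m == 2
    else if (identical(region, "OD_rim")) m == 1
    else if (is.numeric(region)) m == region
    else stop("unknown region: ", region)
  }
  p <- bin(pred); t <- bin(truth)
  out <- list(TP = sum(p & t), TN = sum(!p & !t),
              FP = sum(p & !t), FN = sum(!p & t))
  out$P <- out$TP + out$FN
  out$N <- out$TN + out$FP
  class(out) <- "contingency"
  out
}

#' Sensitivity, specificity and accuracy
#'
#' SEN = TP/P, SPC = TN/N, and the prevalence-weighted accuracy
#' ACC = SEN * P/(P+N) + SPC * N/(P+N), which equals (TP+TN)/(P+N).
#' Ratios with an empty class are reported as NA with a warning.
#'
#' @param t a [contingency()] table.
#' @return named numeric vector `c(SEN, SPC, ACC)`.
#' @export
sen_spc_acc <- function(t) {
  if (t$P == 0 || t$N == 0)
    warning("degenerate contingency table: empty positive or negative class")
  sen <- if (t$P > 0) t$TP / t$P else NA_real_
  spc <- if (t$N > 0) t$TN / t$N else NA_real_
  tot <- t$P + t$N
  acc <- if (tot > 0) (t$TP + t$TN) / tot else NA_real_
  c(SEN = sen, SPC = spc, ACC = acc)
}

#' F1 score, precision and recall
#'
#' Precision = TP/(TP+FP), Recall = TP/P, F1 their harmonic mean. F1 is 0
#' when TP = 0 but predictions or positives exist; undefined ratios are NA
#' with a warning.
#'
#' @param t a [contingency()] table.
#' @return named numeric vector `c(F1, Precision, Recall)`.
#' @export
f1_precision_recall <- function(t) {
  if (t$TP + t$FP == 0 || t$P == 0)
    warning("degenerate contingency table: no predicted or true positives")
  prec <- if (t$TP + t$FP > 0) t$TP / (t$TP + t$FP) else NA_real_
  rec <- if (t$P > 0) t$TP / t$P else NA_real_
  f1 <- if (is.na(prec) || is.na(rec)) NA_real_
        else if (prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  c(F1 = f1, Precision = prec, Recall = rec)
}

#' Radial contour of a segmented region
#'
#' Casts `n_points` equidistant rays from `center` and records, per ray, the
#' sub-pixel distance to the foreground/background crossing (by default the
#' outermost crossing, robust to interior holes). Rays that never meet
#' foreground get radius 0 and are flagged.
#'
#' @param mask binary matrix (logical or 0/1).
#' @param center `c(row, col)` ray origin, typically the region centroid.
#' @param n_points number of equidistant directions (default 24).
#' @param boundary `"outermost"` or `"first"` crossing.
#' @param step ray sampling step in pixels.
#' @return object of class `radial_contour`: center, angles, radii, missed.
#' @export
extract_radial_contour <- function(mask, center, n_points = 24L,
                                   boundary = c("outermost", "first"),
                                   step = 0.25) {
  boundary <- match.arg(boundary)
  mask <- mask != 0
  if (!any(mask)) stop("empty region")
  H <- nrow(mask); W <- ncol(mask)
  rmax <- sqrt(max((c(1, H) - center[1])^2) + max((c(1, W) - center[2])^2))
  rs <- seq(0, rmax + step, by = step)
  angles <- 2 * pi * (seq_len(n_points) - 1) / n_points
  radii <- numeric(n_points)
  missed <- logical(n_points)
  for (k in seq_len(n_points)) {
    qr <- center[1] + rs * sin(angles[k]) - 1
    qc <- center[2] + rs * cos(angles[k]) - 1
    v <- .cpp_warp_sample(mask + 0, qr, qc, 1L, 0) > 0.5
    if (!any(v)) {
      radii[k] <- 0
      missed[k] <- TRUE
      next
    }
    if (boundary == "outermost") {
      i <- max(which(v))
    } else {
      inside <- which(v)
      gap <- which(diff(inside) > 1)
      i <- if (length(gap)) inside[gap[1]] else max(inside)
    }
    # linear interpolation between last foreground and first background sample
    radii[k] <- if (i < length(rs)) (rs[i] + rs[i + 1]) / 2 else rs[i]
  }
  structure(list(center = center, angles = angles, radii = radii,
                 missed = missed),
            class = "radial_contour")
}

#' Boundary localization error
#'
#' Mean absolute per-angle difference, in pixels, between the radial
#' distances of two contours sampled at the same angles from a common
#' centre. 0 is ideal; the measure is symmetric and translation-invariant
#' (contours are expressed relative to their shared centre).
#'
#' @param pred_contour,truth_contour [extract_radial_contour()] objects with
#'   matching centers and angle grids.
#' @return nonnegative scalar (pixels).
#' @export
ble <- function(pred_contour, truth_contour) {
  if (length(pred_contour$angles) != length(truth_contour$angles) ||
      max(abs(pred_contour$angles - truth_contour$angles)) > 1e-9)
    stop("mismatched angle grids")
  if (max(abs(pred_contour$center - truth_contour$center)) > 1e-6)
    stop("contours must share a center point")
  mean(abs(pred_contour$radii - truth_contour$radii))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all score thresholds.
#'
#' @param scores numeric scores (higher = more foreground).
#' @param truth binary ground truth of equal shape.
#' @return AUC in `[0, 1]`, or NA (with a warning) if truth has one class.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("shape mismatch")
  y <- as.vector(truth != 0)
  s <- as.vector(scores)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    warning("single-class truth: AUC undefined")
    return(NA_real_)
  }
  o <- order(s, decreasing = TRUE)
  ys <- y[o]; ss <- s[o]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # threshold boundaries (ties)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

## Per-image segmentation metrics for one region; used by rfc_evaluate().
region_metrics <- function(pred, truth, region, n_points = 24L) {
  tab <- contingency(pred, truth, region)
  ssa <- suppressWarnings(sen_spc_acc(tab))
  f1 <- suppressWarnings(f1_precision_recall(tab))
  b <- NA_real_
  tbin <- if (identical(region, "OD")) truth >= 1 else truth == region_class(region)
  pbin <- if (identical(region, "OD")) pred >= 1 else pred == region_class(region)
  if (any(tbin)) {
    ctr <- c(mean(row(truth)[tbin]), mean(col(truth)[tbin]))
    tc <- extract_radial_contour(tbin, ctr, n_points)
    if (any(pbin)) {
      pc <- extract_radial_contour(pbin, ctr, n_points)
      b <- ble(pc, tc)
    } else {
      # empty prediction: all predicted radii are zero
      pc <- tc; pc$radii[] <- 0
      b <- ble(pc, tc)
    }
  }
  c(F1 = unname(f1["F1"]), BLE = b, SEN = unname(ssa["SEN"]),
    SPC = unname(ssa["SPC"]), ACC = unname(ssa["ACC"]))
}

region_class <- function(region) {
  if (identical(region, "OC")) 2 else if (identical(region, "OD_rim")) 1
  else if (is.numeric(region)) region else 2
}
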