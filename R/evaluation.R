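# CAT08-style centerline scoring. Both curves are resampled to a fine
# common arclength spacing (default 0.03 mm), approximating the
# continuous-curve convention; correspondence is point-to-nearest-point.

EVAL_SPACING <- 0.03
CLINICAL_RADIUS <- 1.5

# resample and return bare point sets used by the marking rules
eval_points <- function(cl, spacing) {
  rs <- resample_centerline(cl, spacing)
  list(xyz = cl_xyz(rs), r = if ("r" %in% names(rs)) rs$r else NULL)
}

pool_tree_points <- function(tree, spacing) {
  parts <- lapply(tree$branches, eval_points, spacing = spacing)
  list(xyz = do.call(rbind, lapply(parts, `[[`, "xyz")),
       r = if (all(!vapply(parts, function(p) is.null(p$r), TRUE)))
         unlist(lapply(parts, `[[`, "r")) else NULL)
}

mark_point_sets <- function(ref, method) {
  if (is.null(ref$r)) {
    stop("reference centerline must carry radii", call. = FALSE)
  }
  d2 <- cross_dist2(ref$xyz, method$xyz)   # n_ref x n_method
  dmin_ref <- sqrt(apply(d2, 1, min))      # ref -> nearest method point
  tpr <- dmin_ref < ref$r
  nearest_ref <- max.col(-t(d2), ties.method = "first")  # per method point
  dmin_method <- sqrt(d2[cbind(nearest_ref, seq_len(nrow(method$xyz)))])
  # method point is TPM iff some reference point has it within that
  # reference point's radius
  within <- sweep(sqrt(d2), 1, ref$r, "<")
  tpm <- apply(within, 2, any)
  list(ref_mark = ifelse(tpr, "TPR", "FN"),
       method_mark = ifelse(tpm, "TPM", "FP"),
       nearest_ref = nearest_ref,
       method_dist = dmin_method)
}

#' Mark centerline points as TPR/FN and TPM/FP
#'
#' Both centerlines are resampled to a fine common arclength spacing. A
#' reference point is a true positive (TPR) iff at least one method point
#' lies within that reference point's radius, else a false negative (FN).
#' A method point is a true positive (TPM) iff at least one reference point
#' has it within the radius defined at that reference point, else a false
#' positive (FP).
#'
#' @param reference a [centerline()] with radii.
#' @param method a [centerline()] (radii not required).
#' @param spacing resampling pitch, mm.
#' @return list of tibbles `ref` (x, y, z, r, mark) and `method`
#'   (x, y, z, mark, nearest_ref, dist).
#' @export
mark_points <- function(reference, method, spacing = EVAL_SPACING) {
  rp <- eval_points(reference, spacing)
  mp <- eval_points(method, spacing)
  mk <- mark_point_sets(rp, mp)
  list(
    ref = tibble::tibble(x = rp$xyz[, 1], y = rp$xyz[, 2], z = rp$xyz[, 3],
                         r = rp$r, mark = mk$ref_mark),
    method = tibble::tibble(x = mp$xyz[, 1], y = mp$xyz[, 2], z = mp$xyz[, 3],
                            mark = mk$method_mark,
                            nearest_ref = mk$nearest_ref,
                            dist = mk$method_dist)
  )
}

#' Total overlap OV
#'
#' `(|TPM| + |TPR|) / (|TPM| + |TPR| + |FN| + |FP|)` over the point marks.
#'
#' @param marks output of [mark_points()].
#' @return scalar in `[0, 1]`.
#' @export
overlap_ov <- function(marks) {
  if (!nrow(marks$ref) || !nrow(marks$method)) {
    stop("marks are empty", call. = FALSE)
  }
  counts_ov(marks$ref$mark, marks$method$mark)
}

counts_ov <- function(ref_mark, method_mark) {
  tpr <- sum(ref_mark == "TPR"); fn <- sum(ref_mark == "FN")
  tpm <- sum(method_mark == "TPM"); fp <- sum(method_mark == "FP")
  (tpm + tpr) / (tpm + tpr + fn + fp)
}

#' Clinically relevant overlap OT
#'
#' OV restricted to the reference sub-polyline from the first to the last
#' point (proximal to distal) with radius at or above 1.5 mm — the part of
#' the vessel assumed clinically relevant. Method points are assigned to
#' that region through their nearest reference point. Returns `NA` with
#' attribute `defined = FALSE` when the reference never reaches 1.5 mm.
#'
#' @inheritParams mark_points
#' @return scalar in `[0, 1]`, or flagged `NA`.
#' @export
overlap_ot <- function(reference, method, spacing = EVAL_SPACING) {
  rp <- eval_points(reference, spacing)
  if (is.null(rp$r)) stop("reference centerline must carry radii", call. = FALSE)
  rel <- which(rp$r >= CLINICAL_RADIUS)
  if (!length(rel)) {
    return(structure(NA_real_, defined = FALSE))
  }
  region <- rel[1]:rel[length(rel)]
  mp <- eval_points(method, spacing)
  mk <- mark_point_sets(rp, mp)
  in_region <- mk$nearest_ref %in% region
  structure(
    counts_ov(mk$ref_mark[region], mk$method_mark[in_region]),
    defined = TRUE)
}

#' Average inside accuracy AI
#'
#' Mean Euclidean distance from each true-positive method point (TPM) to
#' its nearest reference point, in mm. Returns `NA` with attribute
#' `defined = FALSE` when no method point is a true positive. A
#' squared-mean variant (mean of squared distances) is available behind
#' `squared = TRUE`.
#'
#' @param marks output of [mark_points()].
#' @param squared use squared distances.
#' @return mm (or mm^2), or flagged `NA`.
#' @export
accuracy_ai <- function(marks, squared = FALSE) {
  d <- marks$method$dist[marks$method$mark == "TPM"]
  if (!length(d)) return(structure(NA_real_, defined = FALSE))
  structure(if (squared) mean(d^2) else mean(d), defined = TRUE)
}

#' Score a method centerline against a reference
#'
#' Computes the point marks and the OV, OT and AI summaries in one call.
#'
#' @inheritParams mark_points
#' @param squared use squared distances in AI.
#' @return An `eval_report`: list with `marks`, `ov`, `ot`, `ai`,
#'   `ot_defined`, `ai_defined`.
#' @export
evaluate_centerline <- function(reference, method, spacing = EVAL_SPACING,
                                squared = FALSE) {
  marks <- mark_points(reference, method, spacing)
  ov <- overlap_ov(marks)
  ot <- overlap_ot(reference, method, spacing)
  ai <- accuracy_ai(marks, squared = squared)
  structure(list(
    marks = marks, ov = ov,
    ot = as.numeric(ot), ot_defined = isTRUE(attr(ot, "defined")),
    ai = as.numeric(ai), ai_defined = isTRUE(attr(ai, "defined"))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> OV %.3f, OT %s, AI %s\n", x$ov,
              if (x$ot_defined) sprintf("%.3f", x$ot) else "undefined",
              if (x$ai_defined) sprintf("%.3f mm", x$ai) else "undefined"))
  invisible(x)
}

#' @rdname evaluate_centerline
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(ov = x$ov, ot = x$ot, ai = x$ai,
                 ot_defined = x$ot_defined, ai_defined = x$ai_defined)
}

#' @rdname evaluate_centerline
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$marks$ref, set = "reference", .before = 1),
    dplyr::mutate(x$marks$method[, c("x", "y", "z", "mark")],
                  set = "method", .before = 1))
}

#' Score a whole tracked tree against a reference tree
#'
#' Branches of each tree are resampled and pooled into one point set per
#' tree; the point-marking rules then apply across the pooled sets, so a
#' method point lying on any reference branch counts. This is the tree-level
#' overlap used for bifurcating phantoms.
#'
#' @param reference_tree a [vessel_tree()] with radii.
#' @param method_tree a [vessel_tree()] (e.g. from [track_tree()]).
#' @param spacing resampling pitch, mm.
#' @param squared use squared distances in AI.
#' @return An `eval_report` (marks pooled over branches).
#' @export
evaluate_tree <- function(reference_tree, method_tree,
                          spacing = EVAL_SPACING, squared = FALSE) {
  rp <- pool_tree_points(reference_tree, spacing)
  mp <- pool_tree_points(method_tree, spacing)
  if (is.null(rp$r)) stop("reference tree must carry radii", call. = FALSE)
  mk <- mark_point_sets(rp, mp)
  marks <- list(
    ref = tibble::tibble(x = rp$xyz[, 1], y = rp$xyz[, 2], z = rp$xyz[, 3],
                         r = rp$r, mark = mk$ref_mark),
    method = tibble::tibble(x = mp$xyz[, 1], y = mp$xyz[, 2], z = mp$xyz[, 3],
                            mark = mk$method_mark,
                            nearest_ref = mk$nearest_ref,
                            dist = mk$method_dist))
  ov <- counts_ov(mk$ref_mark, mk$method_mark)
  rel <- which(rp$r >= CLINICAL_RADIUS)
  if (length(rel)) {
    region <- rel  # pooled sets have no single proximal-distal order
    in_region <- mk$nearest_ref %in% region
    ot <- counts_ov(mk$ref_mark[region], mk$method_mark[in_region])
    ot_defined <- TRUE
  } else {
    ot <- NA_real_; ot_defined <- FALSE
  }
  ai <- accuracy_ai(marks, squared = squared)
  structure(list(
    marks = marks, ov = ov, ot = ot, ot_defined = ot_defined,
    ai = as.numeric(ai), ai_defined = isTRUE(attr(ai, "defined"))
  ), class = "eval_report")
}

#' Mean distance from a tracked centerline to a reference polyline
#'
#' Average over method points of the distance to the nearest reference
#' point (reference resampled finely first). A direct error measure in mm
#' used by the phantom recovery checks.
#'
#' @param reference a [centerline()].
#' @param method a [centerline()].
#' @param spacing reference resampling pitch, mm.
#' @return mm.
#' @export
mean_centerline_error <- function(reference, method, spacing = 0.05) {
  rp <- eval_points(reference, spacing)
  mean(nearest_gt(cl_xyz(method), rp$xyz)$dist)
}
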