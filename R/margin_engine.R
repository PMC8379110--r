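# Core geometry: periablational margin shells from an exact anisotropic
# Euclidean distance transform, plus the five-class completeness grading.

# squared distance field (mm^2) to the nearest foreground voxel center
.dist_sq <- function(grid) {
  if (sum(grid$mask) == 0L)
    stop("distance map undefined: mask has empty foreground", call. = FALSE)
  .edt_sq(as.integer(grid$mask), dim(grid$mask), grid$spacing)
}

# relative tolerance when thresholding squared distances at a margin;
# absorbs floating-point error in s^2*k^2 sums without ever admitting the
# next-nearest voxel (grid distances are separated far more than 1e-9)
.MARGIN_SQ_TOL <- 1e-9

.within_margin <- function(dsq, m) dsq <= m * m * (1 + .MARGIN_SQ_TOL) + 1e-12

# TRUE if expanding to margin m would reach the array boundary
.clipped_at <- function(dsq, m) {
  d <- dim(dsq)
  face <- c(dsq[1, , ], dsq[d[1], , ], dsq[, 1, ], dsq[, d[2], ],
            dsq[, , 1], dsq[, , d[3]])
  any(.within_margin(face, m))
}

#' Euclidean distance map to a mask
#'
#' Distance from every voxel center to the nearest foreground voxel center,
#' in millimetres, honouring anisotropic spacing. Exactly 0 on foreground.
#' Computed with a separable exact distance transform, so it agrees with
#' brute-force all-pairs center distances to floating-point precision.
#'
#' @param grid A `voxel_grid` with non-empty foreground.
#' @return 3D numeric array of distances (mm), same shape as the mask.
#' @export
distance_map <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  sqrt(.dist_sq(grid))
}

#' Expand a tumor mask by a margin
#'
#' The m-mm expansion is the set of voxels whose center lies within m mm of
#' some tumor voxel center (closed at m: a point exactly m mm away belongs
#' to the m-mm margin). Expansion that would reach the array face is an
#' error, not a silent truncation — clipping would bias the unablated
#' percentage downward; pad the volume instead.
#'
#' @param tumor A `voxel_grid` with non-empty foreground.
#' @param m Margin in mm, >= 0. `m = 0` returns the tumor unchanged.
#' @return A `voxel_grid` of the expanded region.
#' @export
expand_tumor <- function(tumor, m) {
  stopifnot(is_voxel_grid(tumor), is.numeric(m), length(m) == 1L, m >= 0)
  if (m == 0) return(tumor)
  dsq <- .dist_sq(tumor)
  if (.clipped_at(dsq, m))
    stop("margin exceeds available image border (", m,
         " mm); pad the volume", call. = FALSE)
  voxel_grid(array(as.integer(.within_margin(dsq, m)), dim = dim(tumor$mask)),
             tumor$spacing, affine = tumor$affine)
}

#' Margin shell around a tumor
#'
#' The periablational safety-margin shell: the m-mm expansion minus the
#' tumor itself. By construction
#' `volume(shell) = volume(expand) - volume(tumor)` exactly.
#'
#' @inheritParams expand_tumor
#' @return A `voxel_grid` of the shell.
#' @export
margin_shell <- function(tumor, m) {
  ex <- expand_tumor(tumor, m)
  voxel_grid(array(as.integer(ex$mask == 1L & tumor$mask == 0L),
                   dim = dim(tumor$mask)),
             tumor$spacing, affine = tumor$affine)
}

#' Unablated safety-margin percentage
#'
#' The fraction of the m-mm safety-margin shell around the tumor that lies
#' outside the ablation (necrosis) zone, times 100: the volume of the
#' calculated safety margin outside the necrosis zone divided by the total
#' shell volume.
#'
#' @param case An `ablation_case`.
#' @param m Margin in mm, > 0.
#' @return U_m in percent, in [0, 100].
#' @export
unablated_margin_percent <- function(case, m) {
  stopifnot(is_ablation_case(case))
  shell <- margin_shell(case$tumor, m)
  n_shell <- sum(shell$mask)
  if (n_shell == 0L)
    stop("margin shell is empty at ", m,
         " mm (below grid resolution); percentage undefined", call. = FALSE)
  100 * sum(shell$mask == 1L & case$ablation$mask == 0L) / n_shell
}

#' Residual tumor percentage
#'
#' Fraction of tumor volume left outside the ablation zone, times 100.
#' Any residual tumor (above tolerance) makes the ablation incomplete.
#'
#' @param case An `ablation_case`.
#' @return R in percent, in [0, 100].
#' @export
residual_tumor_percent <- function(case) {
  stopifnot(is_ablation_case(case))
  100 * sum(case$tumor$mask == 1L & case$ablation$mask == 0L) /
    sum(case$tumor$mask)
}

#' Five-class ablation completeness grade
#'
#' Grades one (residual %, unablated %) pair: residual tumor above the
#' tolerance is `INCOMPLETE` regardless of the shell; otherwise the
#' unablated margin percentage U maps to `SM100` (U exactly 0),
#' `SM95_100` (0 < U < 5), `SM90_95` (5 <= U <= 10) or `SM_LT90` (U > 10).
#' The bracket [5, 10] is closed on both ends; U = 0 means exactly zero
#' uncovered shell voxels, not a rounded zero.
#'
#' @param residual_pct Residual tumor percentage R, in [0, 100].
#' @param unablated_pct Unablated margin percentage U, in [0, 100];
#'   vectorized.
#' @param residual_tol_pct Residual percentage at or below which the tumor
#'   still counts as fully ablated (default 0: any uncovered tumor voxel is
#'   incomplete).
#' @return Character vector of class labels (see [completeness_classes()]).
#' @export
classify_ablation <- function(residual_pct, unablated_pct,
                              residual_tol_pct = 0) {
  if (any(residual_pct < 0 | residual_pct > 100, na.rm = TRUE) ||
      any(unablated_pct < 0 | unablated_pct > 100, na.rm = TRUE))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  n <- max(length(residual_pct), length(unablated_pct))
  residual_pct <- rep_len(residual_pct, n)
  unablated_pct <- rep_len(unablated_pct, n)
  out <- ifelse(residual_pct > residual_tol_pct, "INCOMPLETE",
         ifelse(unablated_pct == 0, "SM100",
         ifelse(unablated_pct < 5, "SM95_100",
         ifelse(unablated_pct <= 10, "SM90_95", "SM_LT90"))))
  out
}

#' Assess one ablation case over a margin sweep
#'
#' Computes the residual-tumor percentage once and, from a single distance
#' transform of the tumor, the unablated safety-margin percentage and
#' completeness class at every requested margin (default 1-10 mm).
#'
#' @param case An `ablation_case`.
#' @param margins Strictly increasing positive margins in mm.
#' @param residual_tol_mm3 Absolute residual-volume tolerance in mm^3
#'   below which sub-voxel leftovers do not count as incomplete ablation.
#' @return A `margin_assessment`: list with `case_id`, `residual_pct`, and
#'   a data frame `by_margin` (columns `margin_mm`, `unablated_pct`,
#'   `class`). Percentages are kept at full precision; round only in
#'   reports.
#' @export
assess_case <- function(case, margins = 1:10, residual_tol_mm3 = 0) {
  stopifnot(is_ablation_case(case))
  margins <- as.numeric(margins)
  if (length(margins) == 0 || any(margins <= 0) || is.unsorted(margins, strictly = TRUE))
    stop("`margins` must be strictly increasing and positive", call. = FALSE)
  dsq <- .dist_sq(case$tumor)
  if (.clipped_at(dsq, max(margins)))
    stop("margin exceeds available image border (", max(margins),
         " mm); pad the volume", call. = FALSE)
  tum <- case$tumor$mask == 1L
  abl <- case$ablation$mask == 1L
  tol_pct <- 100 * residual_tol_mm3 / (sum(tum) * voxel_volume(case$tumor))
  r <- residual_tumor_percent(case)
  u <- vapply(margins, function(m) {
    in_shell <- .within_margin(dsq, m) & !tum
    n <- sum(in_shell)
    if (n == 0L)
      stop("margin shell is empty at ", m, " mm; percentage undefined",
           call. = FALSE)
    100 * sum(in_shell & !abl) / n
  }, numeric(1))
  structure(list(case_id = case$case_id,
                 residual_pct = r,
                 by_margin = data.frame(
                   margin_mm = margins,
                   unablated_pct = u,
                   class = classify_ablation(r, u, tol_pct),
                   stringsAsFactors = FALSE)),
            class = "margin_assessment")
}

#' @export
print.margin_assessment <- function(x, ...) {
  cat(sprintf("<margin_assessment> '%s': residual tumor %.1f%%\n",
              x$case_id, x$residual_pct))
  df <- x$by_margin
  df$unablated_pct <- round(df$unablated_pct, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten an assessment to one cohort-table row
#'
#' @param x A `margin_assessment` with margins 1..10.
#' @param ... Unused.
#' @return One-row data frame with `case_id`, `residual_pct`, `u1`..`u10`.
#' @export
as.data.frame.margin_assessment <- function(x, ...) {
  u <- setNames(as.list(x$by_margin$unablated_pct),
                paste0("u", x$by_margin$margin_mm))
  cbind(data.frame(case_id = x$case_id, residual_pct = x$residual_pct,
                   stringsAsFactors = FALSE),
        as.data.frame(u))
}

#' Write a per-case JSON report
#'
#' @param x A `margin_assessment`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_assessment_json <- function(x, path) {
  stopifnot(inherits(x, "margin_assessment"))
  by_m <- lapply(seq_len(nrow(x$by_margin)), function(i)
    list(unablated_pct = round(x$by_margin$unablated_pct[i], 1),
         class = x$by_margin$class[i]))
  names(by_m) <- as.character(x$by_margin$margin_mm)
  jsonlite::write_json(
    list(case_id = x$case_id,
         residual_pct = round(x$residual_pct, 1),
         margins = by_m),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
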