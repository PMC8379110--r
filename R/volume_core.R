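#' Construct a voxel grid
#'
#' A `voxel_grid` is the geometric substrate of all volumetrics in this
#' package: a 3D binary mask together with the physical edge lengths of a
#' voxel along each axis, in millimetres. Any nonzero input label is mapped
#' to foreground (1); the mask is stored as an integer array of 0/1.
#'
#' @param mask 3D array; nonzero entries are foreground.
#' @param spacing Numeric length-3, voxel edge lengths in mm; all strictly
#'   positive and finite. CT follow-up imaging in this application typically
#'   has finer in-plane resolution than slice thickness (e.g. 1 x 1 x 3 mm),
#'   so anisotropy is first-class throughout.
#' @param affine Optional 4x4 affine carried through I/O round-trips;
#'   not used in any computation.
#'
#' @return An object of class `voxel_grid` with elements `mask`, `spacing`
#'   and `affine`.
#' @export
voxel_grid <- function(mask, spacing, affine = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)",
         call. = FALSE)
  m <- array(as.integer(mask != 0), dim = dim(mask))
  structure(list(mask = m, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  v <- volume_ml(x)
  cat(sprintf("<voxel_grid> %s voxels @ %s mm; foreground %d (%.2f mL)\n",
              paste(dim(x$mask), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$mask), v[["ml"]]))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Physical volume of a voxel in mm^3
#' @param grid A `voxel_grid`.
#' @return Scalar voxel volume, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Foreground volume of a mask
#'
#' Volume is counted whole-voxel: foreground-voxel count times the physical
#' voxel volume. No partial-volume weighting is applied; a voxel is wholly
#' in or out by its label.
#'
#' @param grid A `voxel_grid`.
#' @return Named numeric: `mm3` and `ml` (= mm3 / 1000).
#' @export
volume_ml <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  mm3 <- sum(grid$mask) * voxel_volume(grid)
  c(mm3 = mm3, ml = mm3 / 1000)
}

#' Read a binary mask from a NIfTI file
#'
#' Spacing is taken from the NIfTI header (`pixdim`); any nonzero voxel
#' becomes foreground. Only 3D volumes are accepted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `voxel_grid`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path, call. = FALSE)
  voxel_grid(array(as.integer(img != 0), dim = dim(img)), sp,
             affine = structure(RNifti::xform(img), code = NULL))
}

#' Write a binary mask to a NIfTI file
#'
#' Round-trip contract: `read_mask(write_mask(g, p))` reproduces the
#' foreground voxel set and the spacing exactly.
#'
#' @param grid A `voxel_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  img <- RNifti::asNifti(grid$mask)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble a co-registered tumor/ablation pair
#'
#' Registration itself is out of scope for this package: masks are assumed
#' already resampled onto one grid, and this constructor asserts that
#' contract. Shapes must be identical and spacings equal to within 1e-6 mm
#' per axis; the tumor mask must be non-empty (an empty ablation is legal
#' and simply yields 100% unablated percentages).
#'
#' @param tumor,ablation `voxel_grid` objects on the same grid.
#' @param case_id Identifier carried into reports.
#' @return An object of class `ablation_case`.
#' @export
validate_pair <- function(tumor, ablation, case_id = "case") {
  stopifnot(is_voxel_grid(tumor), is_voxel_grid(ablation))
  if (!identical(dim(tumor$mask), dim(ablation$mask)))
    stop("masks not co-registered: shape mismatch (",
         paste(dim(tumor$mask), collapse = "x"), " vs ",
         paste(dim(ablation$mask), collapse = "x"), ")", call. = FALSE)
  if (any(abs(tumor$spacing - ablation$spacing) > 1e-6))
    stop("masks not co-registered: spacing mismatch", call. = FALSE)
  if (sum(tumor$mask) == 0L)
    stop("tumor mask is empty", call. = FALSE)
  structure(list(case_id = as.character(case_id),
                 tumor = tumor, ablation = ablation),
            class = "ablation_case")
}

is_ablation_case <- function(x) inherits(x, "ablation_case")

#' @export
print.ablation_case <- function(x, ...) {
  cat(sprintf("<ablation_case> '%s': tumor %.2f mL, ablation %.2f mL on %s grid\n",
              x$case_id, volume_ml(x$tumor)[["ml"]],
              volume_ml(x$ablation)[["ml"]],
              paste(dim(x$tumor$mask), collapse = "x")))
  invisible(x)
}
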