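# Voxel grid and tissue label bookkeeping.
#
# Label encoding (integer array, one code per voxel):
#   0 background, 1 liver, 2 tumor, 3 vessel,
#   10 + k active segment of electrode k, 40 + k insulated shaft of
#   electrode k (k = 1..30). The encoding is exported with every label map
#   as a JSON sidecar so files remain self-describing.

.LBL <- list(background = 0L, liver = 1L, tumor = 2L, vessel = 3L)
.LBL_ACTIVE_BASE <- 10L
.LBL_INSUL_BASE <- 40L
.LBL_MAX_ELECTRODES <- 30L

#' Construct a voxel grid
#'
#' @param extent physical extent per axis, mm (length-3, positive).
#' @param spacing voxel spacing per axis, mm (length-3 or scalar, positive).
#' @param origin position of the grid corner, mm.
#' @return A `vox_grid` with `shape` (voxel counts, `ceiling(extent/spacing)`
#'   per axis), `spacing` and `origin`.
#' @examples
#' g <- build_grid(c(80, 80, 80), 1)
#' g$shape            # 80 80 80
#' voxel_volume(g)    # 1 mm^3
#' @export
build_grid <- function(extent, spacing, origin = c(0, 0, 0)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  extent <- rep_len(as.numeric(extent), 3L)
  if (any(!is.finite(extent)) || any(extent <= 0))
    stop("grid extent must be positive and finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be positive and finite")
  shape <- as.integer(ceiling(extent / spacing - 1e-9))
  shape <- pmax(shape, 2L)
  structure(list(shape = shape, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d voxels, spacing %s mm, %s voxels total\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              format(prod(x$shape), big.mark = ",")))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `vox_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Total voxel count of a grid
#' @param grid a `vox_grid`.
#' @export
n_voxels <- function(grid) prod(grid$shape)

# Voxel-center coordinates along one axis (mm). 1-based voxel index i has
# its center at origin + (i - 1/2) * spacing.
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

# Full coordinate arrays; used by the rasterizers. ~3 doubles per voxel.
coordinate_arrays <- function(grid) {
  sh <- grid$shape
  xs <- axis_centers(grid, 1); ys <- axis_centers(grid, 2); zs <- axis_centers(grid, 3)
  list(x = array(rep(xs, times = sh[2] * sh[3]), dim = sh),
       y = array(rep(rep(ys, each = sh[1]), times = sh[3]), dim = sh),
       z = array(rep(zs, each = sh[1] * sh[2]), dim = sh))
}

point_in_grid <- function(grid, p) {
  lo <- grid$origin
  hi <- grid$origin + grid$shape * grid$spacing
  all(p >= lo) && all(p <= hi)
}

label_code <- function(label, index = NULL) {
  if (label %in% names(.LBL)) return(.LBL[[label]])
  if (is.null(index)) stop("electrode labels need an electrode index")
  if (index < 1L || index > .LBL_MAX_ELECTRODES)
    stop("electrode index out of range 1..", .LBL_MAX_ELECTRODES)
  switch(label,
         electrode_active = .LBL_ACTIVE_BASE + as.integer(index),
         electrode_insulated = .LBL_INSUL_BASE + as.integer(index),
         stop("unknown label: ", label))
}

is_active_code <- function(codes)
  codes > .LBL_ACTIVE_BASE & codes <= .LBL_ACTIVE_BASE + .LBL_MAX_ELECTRODES
is_insulated_code <- function(codes)
  codes > .LBL_INSUL_BASE & codes <= .LBL_INSUL_BASE + .LBL_MAX_ELECTRODES
is_tissue_code <- function(codes) codes %in% c(1L, 2L, 3L)

# Human-readable name per code, vectorized.
label_name <- function(codes) {
  out <- rep("background", length(codes))
  out[codes == 1L] <- "liver"; out[codes == 2L] <- "tumor"; out[codes == 3L] <- "vessel"
  act <- is_active_code(codes); ins <- is_insulated_code(codes)
  out[act] <- paste0("electrode_active_", codes[act] - .LBL_ACTIVE_BASE)
  out[ins] <- paste0("electrode_insulated_", codes[ins] - .LBL_INSUL_BASE)
  out
}
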