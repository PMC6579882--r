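#' @keywords internal
"_PACKAGE"

# Movement and condition labels used throughout. Conditions are body part x
# body side; the factorial analysis uses the three contralateral movements
# per hemisphere.
MOVEMENTS <- c("foot", "hand", "face")
SIDES <- c("left", "right")
RESOLUTIONS <- c(1.5, 2, 3)

#' Condition labels of the motor paradigm
#'
#' The paradigm crosses three body parts (foot, hand, lower face) with two
#' body sides, yielding six movement conditions.
#'
#' @return Character vector of six condition labels, body part major.
#' @export
condition_labels <- function() {
  as.vector(t(outer(MOVEMENTS, SIDES, paste, sep = "_")))
}

#' Acquisition protocol specification
#'
#' Describes one EPI protocol: isotropic voxel size, volume repetition time,
#' number of volumes, encoding scheme and the retained slab geometry. All
#' presets retain the same head-foot coverage so that protocols are compared
#' over an identical anatomical extent.
#'
#' @param name Protocol label, e.g. `"1.5mm"`.
#' @param voxel_size Isotropic voxel size in mm.
#' @param volume_tr_ms Volume repetition time in milliseconds.
#' @param n_volumes Number of volumes acquired.
#' @param encoding `"2D"` or `"3D"` EPI encoding.
#' @param retained_slices Number of slices retained after discarding
#'   oversampled slices.
#' @param slice_thickness Slice thickness in mm (equals voxel size for the
#'   isotropic presets).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, voxel_size, volume_tr_ms, n_volumes,
                          encoding = c("3D", "2D"),
                          retained_slices, slice_thickness = voxel_size) {
  encoding <- match.arg(encoding)
  stopifnot(volume_tr_ms > 0, n_volumes > 0, voxel_size > 0,
            retained_slices > 0, slice_thickness > 0)
  structure(list(name = name, voxel_size = voxel_size,
                 volume_tr_ms = volume_tr_ms, n_volumes = n_volumes,
                 encoding = encoding, retained_slices = retained_slices,
                 slice_thickness = slice_thickness),
            class = "protocol_spec")
}

#' Head-foot coverage of a protocol
#'
#' @param protocol A [protocol_spec()].
#' @return Coverage in mm (retained slices times slice thickness).
#' @export
coverage_mm <- function(protocol) {
  protocol$retained_slices * protocol$slice_thickness
}

#' The three study acquisition protocols
#'
#' Presets for the 1.5 mm and 2 mm 3D-EPI and the 3 mm 2D-EPI protocols:
#' (1.5 mm, TR 4032 ms, 176 volumes), (2 mm, TR 2704 ms, 263 volumes),
#' (3 mm, TR 1980 ms, 359 volumes). Retained slice counts are 60/45/30 so
#' that every preset covers 90 mm in the head-foot direction.
#'
#' @return Named list of three `protocol_spec` objects, finest first.
#' @export
protocol_presets <- function() {
  list(
    "1.5mm" = protocol_spec("1.5mm", 1.5, 4032, 176, "3D", retained_slices = 60),
    "2mm"   = protocol_spec("2mm",   2.0, 2704, 263, "3D", retained_slices = 45),
    "3mm"   = protocol_spec("3mm",   3.0, 1980, 359, "2D", retained_slices = 30)
  )
}

#' Block-paradigm specification
#'
#' Defaults follow the motor task: 18 active blocks of 16 s (3 per
#' condition), rest blocks of equal duration interleaved, and a 3 s visually
#' cued preparation period before each active block, movements paced at 1 Hz.
#'
#' @param conditions Condition labels (default [condition_labels()]).
#' @param blocks_per_condition Active blocks per condition.
#' @param block_duration Active block duration, seconds.
#' @param rest_duration Rest block duration, seconds.
#' @param prep_duration Preparation-period duration, seconds.
#' @param pace_hz Movement pacing rate, Hz (metadata only).
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(conditions = condition_labels(),
                          blocks_per_condition = 3,
                          block_duration = 16, rest_duration = 16,
                          prep_duration = 3, pace_hz = 1) {
  if (length(conditions) < 1 || blocks_per_condition < 1)
    stop("paradigm must have at least one condition and one block per condition")
  stopifnot(block_duration > 0, rest_duration >= 0, prep_duration >= 0)
  structure(list(conditions = conditions,
                 blocks_per_condition = blocks_per_condition,
                 block_duration = block_duration,
                 rest_duration = rest_duration,
                 prep_duration = prep_duration, pace_hz = pace_hz),
            class = "paradigm_spec")
}

#' Cells of the movement-by-resolution factorial
#'
#' The pattern component analysis treats the 3 contralateral movements at the
#' 3 acquisition resolutions as a 3 x 3 factorial with p = 9 cells. Cell
#' order is fixed package-wide as resolution-major, movement-minor:
#' (1.5, foot), (1.5, hand), (1.5, face), (2, foot), ... (3, face).
#'
#' @return Data frame with columns `cell`, `resolution`, `movement`.
#' @export
factorial_cells <- function() {
  data.frame(cell = 1:9,
             resolution = rep(RESOLUTIONS, each = 3),
             movement = rep(MOVEMENTS, times = 3),
             stringsAsFactors = FALSE)
}

#' Map a (movement, resolution) pair to its factorial cell index
#'
#' @param movement One of `"foot"`, `"hand"`, `"face"`.
#' @param resolution One of 1.5, 2, 3 (mm).
#' @return Integer cell index in 1..9.
#' @export
cell_index <- function(movement, resolution) {
  im <- match(movement, MOVEMENTS)
  ir <- match(resolution, RESOLUTIONS)
  if (anyNA(im) || anyNA(ir)) stop("unknown movement or resolution")
  as.integer((ir - 1L) * 3L + im)
}

#' Within-resolution movement pairs and within-movement resolution pairs
#'
#' Enumerates the two pair families used for Index-of-Similarity reporting:
#' `"within_resolution"` pairs the three movements inside each resolution
#' (9 pairs), `"within_movement"` pairs the three resolutions inside each
#' movement (9 pairs).
#'
#' @param family `"within_resolution"` or `"within_movement"`.
#' @return Data frame with columns `cell_a`, `cell_b`, `group` (the shared
#'   level), `pair` (label of the differing levels).
#' @export
cell_pairs <- function(family = c("within_resolution", "within_movement")) {
  family <- match.arg(family)
  cells <- factorial_cells()
  out <- NULL
  if (family == "within_resolution") {
    for (res in RESOLUTIONS) {
      idx <- cells$cell[cells$resolution == res]
      cmb <- utils::combn(idx, 2)
      out <- rbind(out, data.frame(
        cell_a = cmb[1, ], cell_b = cmb[2, ], group = paste0(res, "mm"),
        pair = paste(cells$movement[cmb[1, ]], cells$movement[cmb[2, ]],
                     sep = "-")))
    }
  } else {
    for (mov in MOVEMENTS) {
      idx <- cells$cell[cells$movement == mov]
      cmb <- utils::combn(idx, 2)
      out <- rbind(out, data.frame(
        cell_a = cmb[1, ], cell_b = cmb[2, ], group = mov,
        pair = paste0(cells$resolution[cmb[1, ]], "mm-",
                      cells$resolution[cmb[2, ]], "mm")))
    }
  }
  out
}

#' 3D/4D volume with a world-coordinate affine
#'
#' Light container pairing an intensity array with its 4x4 voxel-to-mm
#' affine. Voxel indices are 0-based in world-coordinate computations, so
#' world = affine %*% c(i, j, k, 1) for the voxel at R index (i+1, j+1, k+1).
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix (mm).
#' @param space Free-text space label.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, affine = diag(4), space = "synthetic") {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L),
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(data = data, affine = affine, space = space),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " | voxel size ", paste(round(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3),
                              collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Labeled region-of-interest set
#'
#' @param labels 3D integer array; 0 = background, k = ROI k.
#' @param names Character vector naming labels 1..length(names).
#' @param affine Voxel-to-world affine shared with the functional grid.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, names, affine = diag(4)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  counts <- tabulate(labels[labels > 0], nbins = length(names))
  if (any(counts == 0))
    stop("empty ROI(s): ", paste(names[counts == 0], collapse = ", "))
  structure(list(labels = labels, names = names, affine = affine),
            class = "roi_set")
}

#' Binary mask of one named ROI
#' @param rois An [roi_set()].
#' @param name ROI name.
#' @return Logical 3D array.
#' @export
roi_mask <- function(rois, name) {
  k <- match(name, rois$names)
  if (is.na(k)) stop("unknown ROI: ", name)
  rois$labels == k
}

# internal: run code with a private RNG state so generators are pure
# functions of (parameters, seed) and never disturb the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}
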