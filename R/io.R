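# Standard-format I/O (NIfTI-1 volumes, tab-separated event tables,
# whitespace-delimited motion traces, YAML-style config) and spatial
# Gaussian smoothing.

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A [volume_image()] carrying the data array and sform affine.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI at ", path, ": ",
                                           conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_image(as.array(img), aff, space = "file")
}

#' Write a [volume_image()] as NIfTI-1
#'
#' @param image A [volume_image()].
#' @param path Output path.
#' @param datatype Storage type (`"float"` = float32, `"double"`).
#' @return The path, invisibly.
#' @export
write_nifti <- function(image, path, datatype = "float") {
  stopifnot(inherits(image, "volume_image"))
  img <- RNifti::asNifti(image$data)
  RNifti::pixdim(img) <- sqrt(colSums(image$affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(image$affine, code = 2L)
  RNifti::qform(img) <- structure(image$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write an event table as tab-separated text
#'
#' Columns: onset, duration, trial_type, event_class (the 3-column
#' onset/duration/trial_type convention plus the event class).
#'
#' @param events Event table from [make_paradigm()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$condition,
                    event_class = events$event_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated event table
#'
#' @param path Path to a TSV with onset, duration, trial_type and
#'   optionally event_class columns.
#' @return An `event_table` data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("event table must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(onset = df$onset, duration = df$duration,
                    condition = df$trial_type,
                    event_class = if ("event_class" %in% names(df))
                      df$event_class else
                        ifelse(df$trial_type == "rest", "rest", "active"))
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#' @param trace n_volumes x 6 matrix.
#' @param path File path.
#' @return The path (write) or the matrix (read).
#' @export
write_motion <- function(trace, path) {
  utils::write.table(format(trace, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion trace must have 6 columns, got ", ncol(m))
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

# 1D Gaussian band matrix with edge renormalization (rows sum to 1), so a
# constant image is exactly preserved
gauss_band <- function(d, sigma_vox) {
  if (sigma_vox == 0) return(diag(d))
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-half:half, sd = sigma_vox)
  B <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= d
    B[i, j[ok]] <- k[ok]
    B[i, ] <- B[i, ] / sum(B[i, ])
  }
  B
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths each volume with a separable Gaussian of the requested full
#' width at half maximum in mm, converted per axis to voxels through the
#' affine scales (sigma = fwhm / (2 sqrt(2 log 2))). Kernel rows are
#' renormalized at the edges, so constant images are preserved exactly.
#' `fwhm_mm = 0` is the identity.
#'
#' @param image A 3D or 4D [volume_image()].
#' @param fwhm_mm Kernel FWHM in mm.
#' @return Smoothed [volume_image()].
#' @export
gaussian_smooth <- function(image, fwhm_mm) {
  stopifnot(inherits(image, "volume_image"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(image)
  A <- image$affine[1:3, 1:3]
  if (max(abs(A[upper.tri(A)]), abs(A[lower.tri(A)])) > 1e-6 * max(abs(A)))
    stop("sheared/oblique affines are not supported for smoothing")
  scales <- sqrt(colSums(A^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / scales
  d <- dim(image$data)
  B <- lapply(1:3, function(a) gauss_band(d[a], sigma_vox[a]))
  smooth3 <- function(vol) {
    v <- B[[1]] %*% matrix(vol, d[1])                     # along x
    v <- array(v, d[1:3])
    v <- aperm(array(B[[2]] %*% matrix(aperm(v, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))          # along y
    v <- aperm(array(B[[3]] %*% matrix(aperm(v, c(3, 1, 2)), d[3]),
                     d[c(3, 1, 2)]), c(2, 3, 1))          # along z
    v
  }
  if (length(d) == 3L) {
    out <- smooth3(image$data)
  } else {
    out <- array(0, d)
    for (t in seq_len(d[4])) out[, , , t] <- smooth3(image$data[, , , t])
  }
  volume_image(out, image$affine, image$space)
}

#' Write a run configuration as plain-text key: value lines
#' @param config A named list (see [run_config()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) if (length(v) > 1)
    paste0("[", paste(v, collapse = ", "), "]") else as.character(v)
  lines <- vapply(names(config), function(k) paste0(k, ": ", fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
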