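#' Construct a BOLD series
#'
#' A per-subject 4D resting-state series stored as a time x voxel matrix in
#' column-major voxel order on a common grid.
#'
#' @param grid a [volume_grid()].
#' @param data numeric matrix, timepoints x `prod(grid$dim)` voxels.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id optional identifier.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(grid, data, tr_seconds, subject_id = NA_character_) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == n_voxels(grid), tr_seconds > 0)
  structure(list(grid = grid, data = data, tr = as.numeric(tr_seconds),
                 subject_id = as.character(subject_id)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s: %d timepoints on %s, TR = %g s\n",
              x$subject_id, nrow(x$data), format(x$grid), x$tr))
  invisible(x)
}

n_timepoints <- function(bold) nrow(bold$data)

#' Read / write a 4D BOLD NIfTI volume
#'
#' @param path NIfTI-1 file with 4 dimensions.
#' @param tr_seconds repetition time; if `NULL`, taken from the NIfTI
#'   header (`pixdim[4]`).
#' @param drop_initial number of initial volumes to discard before
#'   analysis (signal-equilibration dummies); default 0 because synthetic
#'   series start at equilibrium.
#' @inheritParams bold_series
#' @return `read_bold`: a [bold_series()].
#' @export
read_bold <- function(path, tr_seconds = NULL, drop_initial = 0L,
                      subject_id = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L) stop("expected a 4D NIfTI volume: ", path)
  grid <- grid_from_nifti(im)
  if (is.null(tr_seconds)) tr_seconds <- RNifti::pixdim(im)[4]
  dat <- t(matrix(as.vector(im), nrow = prod(d[1:3]), ncol = d[4]))
  if (drop_initial > 0L) {
    if (drop_initial >= nrow(dat)) stop("drop_initial leaves no volumes")
    dat <- dat[-seq_len(drop_initial), , drop = FALSE]
  }
  bold_series(grid, dat, tr_seconds, subject_id)
}

#' @rdname read_bold
#' @param bold a [bold_series()] to write.
#' @export
write_bold <- function(bold, path) {
  arr <- array(t(bold$data), dim = c(bold$grid$dim, nrow(bold$data)))
  im <- RNifti::asNifti(
    arr,
    reference = list(pixdim = c(-1, bold$grid$voxel_size, bold$tr,
                                0, 0, 0)),
    datatype = "float")
  im <- RNifti::`sform<-`(im, structure(bold$grid$affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = "float")
  invisible(path)
}

#' Read a rigid-body motion trace
#'
#' Six columns per timepoint: translations in mm (x, y, z) then rotations
#' in radians, the realignment-parameter convention.
#'
#' @param path whitespace-delimited text file, 6 columns, no header.
#' @return A timepoints x 6 numeric matrix with standard column names.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  as_motion(m)
}

as_motion <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 6L)
    stop("motion trace must have exactly 6 columns, got ", ncol(m))
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' Framewise displacement (Power convention)
#'
#' Volume-to-volume head movement: the sum of absolute backward differences
#' of the three translations (mm) plus the three rotations converted to mm
#' of arc on a 50 mm sphere. The first frame has FD = 0.
#'
#' @param motion timepoints x 6 matrix, translations (mm) then rotations
#'   (radians).
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @return Numeric vector of per-timepoint FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as_motion(motion)
  if (nrow(motion) < 2L) stop("motion trace needs at least 2 timepoints")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Friston-24 motion regressor expansion
#'
#' The 6 rigid-body parameters R, their squares, their one-volume lags and
#' the squared lags, in that column order; lagged rows at t = 0 are zero.
#'
#' @inheritParams framewise_displacement
#' @return timepoints x 24 numeric matrix.
#' @export
friston24 <- function(motion) {
  motion <- as_motion(motion)
  if (nrow(motion) < 2L) stop("motion trace needs at least 2 timepoints")
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag, lag^2)
  colnames(out) <- c(paste0("mot_", colnames(motion)),
                     paste0("mot_", colnames(motion), "_sq"),
                     paste0("mot_", colnames(motion), "_lag"),
                     paste0("mot_", colnames(motion), "_lagsq"))
  out
}

mask_mean_course <- function(bold, mask, what) {
  check_same_grid(bold$grid, mask$grid, paste("BOLD and", what, "mask"))
  idx <- mask_which(mask)
  if (length(idx) == 0L) stop("empty ", what, " mask")
  rowMeans(bold$data[, idx, drop = FALSE])
}

#' Build the nuisance regression design
#'
#' Columns: intercept; linear drift (0..1 over the run); the Friston-24
#' motion expansion; one one-hot spike regressor per frame whose framewise
#' displacement exceeds `fd_spike_mm` (strictly greater, matching the
#' > 0.5 mm scrubbing convention); and the mean time courses over the
#' brain (global signal), white-matter and CSF masks.
#'
#' @param motion timepoints x 6 motion matrix.
#' @param fd per-timepoint framewise displacement from
#'   [framewise_displacement()]; computed from `motion` when `NULL`.
#' @param bold the subject's [bold_series()].
#' @param brain,wm,csf [binary_mask()]s on the BOLD grid.
#' @param fd_spike_mm spike threshold in mm (default 0.5).
#' @return timepoints x regressors numeric matrix with labelled columns.
#' @export
build_nuisance_design <- function(motion, fd = NULL, bold, brain, wm, csf,
                                  fd_spike_mm = 0.5) {
  motion <- as_motion(motion)
  tp <- n_timepoints(bold)
  if (nrow(motion) != tp)
    stop("motion trace has ", nrow(motion), " rows but BOLD has ", tp)
  if (is.null(fd)) fd <- framewise_displacement(motion)
  stopifnot(length(fd) == tp)

  drift <- if (tp > 1L) (seq_len(tp) - 1) / (tp - 1) else 0
  X <- cbind(intercept = rep(1, tp), drift = drift, friston24(motion))

  spikes <- which(fd > fd_spike_mm)
  if (length(spikes)) {
    S <- matrix(0, tp, length(spikes))
    S[cbind(spikes, seq_along(spikes))] <- 1
    colnames(S) <- paste0("spike_", spikes)
    X <- cbind(X, S)
  }
  X <- cbind(X,
             global = mask_mean_course(bold, brain, "brain"),
             wm = mask_mean_course(bold, wm, "white-matter"),
             csf = mask_mean_course(bold, csf, "CSF"))
  X
}

#' Regress nuisance covariates out of a BOLD series
#'
#' Per-voxel ordinary least squares; returns the residual series. Exactly
#' duplicated columns are dropped silently; any remaining rank deficiency
#' is an error naming the collinear columns.
#'
#' @param bold a [bold_series()].
#' @param design timepoints x regressors matrix (see
#'   [build_nuisance_design()]).
#' @return A [bold_series()] of residuals, orthogonal to every design
#'   column.
#' @export
regress_nuisance <- function(bold, design) {
  bold$data <- resid_matrix(design, bold$data, n_timepoints(bold))
  bold
}

resid_matrix <- function(design, Y, tp) {
  design <- as.matrix(design)
  if (nrow(design) != tp)
    stop("design has ", nrow(design), " rows but BOLD has ", tp)
  design <- design[, !duplicated(t(design)), drop = FALSE]
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("nuisance design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, Y)
}

#' Band-pass filter a BOLD series
#'
#' Ideal (frequency-domain) filter: Fourier coefficients at frequencies
#' outside `[low_hz, high_hz]` are zeroed — including the DC component —
#' and the series is inverse-transformed. This is the fully deterministic
#' rectangular filter used by the common resting-state toolchains.
#'
#' @param bold a [bold_series()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.01 and 0.1);
#'   `high_hz` must not exceed the Nyquist frequency `1/(2 TR)`.
#' @return The filtered [bold_series()].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.1) {
  tp <- n_timepoints(bold)
  nyquist <- 1 / (2 * bold$tr)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyquist + 1e-12)
    stop(sprintf("high_hz = %g Hz exceeds the Nyquist frequency %g Hz",
                 high_hz, nyquist))
  bold$data <- bandpass_matrix(bold$data, bold$tr, low_hz, high_hz)
  bold
}

bandpass_matrix <- function(Y, tr, low_hz, high_hz) {
  tp <- nrow(Y)
  k <- 0:(tp - 1)
  freq <- pmin(k, tp - k) / (tp * tr)
  keep <- freq >= low_hz & freq <= high_hz & k != 0L
  ft <- stats::mvfft(Y)
  ft[!keep, ] <- 0
  Re(stats::mvfft(ft, inverse = TRUE)) / tp
}

#' Temporal cleaning of one subject's BOLD series
#'
#' Nuisance regression followed by band-pass filtering (the default
#' order); `filter_first = TRUE` swaps the two stages. The temporal model
#' is applied to the in-brain voxels; voxels outside the brain mask are
#' set to zero (they carry no analysable signal and are excluded from
#' every downstream stage).
#'
#' @inheritParams build_nuisance_design
#' @inheritParams bandpass
#' @param filter_first apply the band-pass before the regression.
#' @return The cleaned [bold_series()].
#' @export
clean_bold <- function(bold, motion, brain, wm, csf, fd_spike_mm = 0.5,
                       low_hz = 0.01, high_hz = 0.1, filter_first = FALSE) {
  design <- build_nuisance_design(motion, fd = NULL, bold = bold,
                                  brain = brain, wm = wm, csf = csf,
                                  fd_spike_mm = fd_spike_mm)
  tp <- n_timepoints(bold)
  bidx <- mask_which(brain)
  X <- bold$data[, bidx, drop = FALSE]
  if (filter_first) {
    X <- bandpass_matrix(X, bold$tr, low_hz, high_hz)
    X <- resid_matrix(design, X, tp)
  } else {
    X <- resid_matrix(design, X, tp)
    X <- bandpass_matrix(X, bold$tr, low_hz, high_hz)
  }
  out <- matrix(0, tp, n_voxels(bold$grid))
  out[, bidx] <- X
  bold$data <- out
  bold
}

#' Motion screening of one subject
#'
#' A subject passes when the maximal absolute translation stays below
#' `trans_limit_mm` on every axis and the maximal absolute rotation below
#' `rot_limit_deg` (rotations stored in radians are compared in degrees).
#'
#' @inheritParams framewise_displacement
#' @param trans_limit_mm,rot_limit_deg screening limits (defaults 2 mm, 2
#'   degrees).
#' @return Logical scalar with attribute `"reason"` (`NA` when passing).
#' @export
motion_screen <- function(motion, trans_limit_mm = 2, rot_limit_deg = 2) {
  motion <- as_motion(motion)
  max_trans <- max(abs(motion[, 1:3]))
  max_rot_deg <- max(abs(motion[, 4:6])) * 180 / pi
  ok <- max_trans < trans_limit_mm && max_rot_deg < rot_limit_deg
  structure(ok, reason = if (ok) NA_character_ else "motion")
}
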