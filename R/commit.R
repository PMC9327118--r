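#' Gradient table (FSL-style bvals/bvecs)
#'
#' Bundles the diffusion-encoding b-values and unit gradient directions of
#' an acquisition. The default mirrors a standard single-shell protocol:
#' 64 directions at b = 1000 s/mm^2 plus 9 b = 0 volumes.
#'
#' @param b_values numeric vector of b-values (s/mm^2), one per volume.
#' @param directions numeric matrix, volumes x 3; rows must be unit-norm
#'   wherever the b-value is positive (b = 0 rows may be zero vectors).
#' @return An object of class `gradient_table` with elements `b_values`
#'   and `directions`.
#' @export
gradient_table <- function(b_values, directions) {
  directions <- as.matrix(directions)
  if (length(b_values) != nrow(directions) || ncol(directions) != 3L)
    stop("gradient table needs one 3-vector per b-value")
  if (!any(b_values == 0))
    stop("gradient table must contain at least one b = 0 volume")
  nrm <- sqrt(rowSums(directions^2))
  bad <- b_values > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop("non-unit gradient direction in volume(s) ",
         paste(which(bad), collapse = ", "))
  structure(list(b_values = as.numeric(b_values), directions = directions),
            class = "gradient_table")
}

#' Default single-shell gradient table
#'
#' 9 b = 0 volumes followed by `n_dir` directions at `b` s/mm^2, spread
#' over the sphere by a deterministic Fibonacci lattice.
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param b shell b-value in s/mm^2.
#' @param n_b0 number of non-diffusion-weighted volumes.
#' @return A `gradient_table`.
#' @export
default_gradients <- function(n_dir = 64L, b = 1000, n_b0 = 9L) {
  i <- seq_len(n_dir)
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - (2 * i - 1) / n_dir
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(theta), r * sin(theta), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_table(c(rep(0, n_b0), rep(b, n_dir)),
                 rbind(matrix(0, n_b0, 3), dirs))
}

#' Ball-and-stick compartment model parameters
#'
#' Two-compartment diffusion model: an anisotropic "stick" for the
#' intra-axonal space (axial diffusivity only, zero perpendicular
#' diffusivity) and isotropic "balls" for free/hindered water. Defaults:
#' stick axial diffusivity 1.7e-3 mm^2/s; ball diffusivities 1.7e-3 and
#' 3.0e-3 mm^2/s.
#'
#' @param d_parallel stick axial diffusivity (mm^2/s).
#' @param d_iso numeric vector of ball diffusivities (mm^2/s).
#' @return An object of class `commit_model`.
#' @export
commit_model <- function(d_parallel = 1.7e-3, d_iso = c(1.7e-3, 3.0e-3)) {
  if (d_parallel < 0 || any(d_iso < 0)) stop("diffusivities must be >= 0")
  structure(list(d_parallel = d_parallel, d_perp = 0, d_iso = d_iso),
            class = "commit_model")
}

#' Stick compartment signal attenuation
#'
#' exp(-b * d_parallel * (g . u)^2) for gradient direction g and fibre
#' tangent u. The perpendicular diffusivity is fixed at zero, so only the
#' component of diffusion along the fibre attenuates the signal.
#'
#' @param b b-value (s/mm^2).
#' @param g gradient direction, unit 3-vector (ignored when b = 0).
#' @param u fibre tangent, unit 3-vector.
#' @param model a [commit_model()].
#' @return Attenuation in \[0, 1\].
#' @export
stick_attenuation <- function(b, g, u, model = commit_model()) {
  if (b < 0) stop("b must be >= 0")
  if (b == 0) return(1)
  if (abs(sum(g^2) - 1) > 1e-6 || abs(sum(u^2) - 1) > 1e-6)
    stop("g and u must be unit vectors when b > 0")
  exp(-b * model$d_parallel * sum(g * u)^2)
}

#' Ball compartment signal attenuation
#'
#' Isotropic mono-exponential decay exp(-b * d).
#'
#' @param b b-value (s/mm^2).
#' @param d isotropic diffusivity (mm^2/s).
#' @return Attenuation in (0, 1\].
#' @export
ball_attenuation <- function(b, d) {
  if (b < 0 || d < 0) stop("b and d must be >= 0")
  exp(-b * d)
}

# Linear index of voxel rows (matrix k x 3, 1-based) in a grid.
voxel_index <- function(vox, grid_shape) {
  (vox[, 1] - 1) + grid_shape[1] * ((vox[, 2] - 1) +
    grid_shape[2] * (vox[, 3] - 1)) + 1L
}

#' Build the forward linear operator of the decomposition
#'
#' Maps per-streamline intra-axonal signal fractions plus per-voxel
#' isotropic fractions to the predicted diffusion signal in every voxel
#' and volume. Column k (streamline k) is supported on the voxels the
#' streamline traverses, with entries segment length x stick attenuation
#' for the voxel's local tangent. One isotropic column per voxel per ball
#' diffusivity holds the ball attenuation.
#'
#' @param tractogram a `tractogram` (see [gen_toy_tractogram()]).
#' @param gradients a [gradient_table()].
#' @param model a [commit_model()].
#' @return List of class `commit_operator`: dense matrix `A`
#'   ((n_vox*n_vol) x (n_streamlines + n_iso*n_vox)), plus the index
#'   bookkeeping needed to reshape signals.
#' @export
build_operator <- function(tractogram, gradients, model = commit_model()) {
  gs <- tractogram$grid_shape
  n_vox <- prod(gs)
  bv <- gradients$b_values
  n_vol <- length(bv)
  n_str <- length(tractogram$streamlines)
  n_iso <- length(model$d_iso)
  if (n_str == 0L) message("empty tractogram: operator has iso columns only")

  A <- matrix(0, n_vox * n_vol, n_str + n_iso * n_vox)
  # volume-major blocks: row index = (vol - 1) * n_vox + voxel
  for (k in seq_len(n_str)) {
    s <- tractogram$streamlines[[k]]
    vi <- voxel_index(s$voxels, gs)
    if (any(vi < 1 | vi > n_vox)) stop("streamline voxel outside grid")
    for (v in seq_len(n_vol)) {
      att <- if (bv[v] == 0) rep(1, nrow(s$tangents)) else
        exp(-bv[v] * model$d_parallel *
              (s$tangents %*% gradients$directions[v, ])^2)
      A[(v - 1L) * n_vox + vi, k] <- A[(v - 1L) * n_vox + vi, k] +
        s$seg_lengths * as.numeric(att)
    }
  }
  for (j in seq_len(n_iso)) {
    att <- exp(-bv * model$d_iso[j])
    col0 <- n_str + (j - 1L) * n_vox
    for (v in seq_len(n_vol)) {
      rows <- (v - 1L) * n_vox + seq_len(n_vox)
      A[cbind(rows, col0 + seq_len(n_vox))] <- att[v]
    }
  }
  structure(list(A = A, n_vox = n_vox, n_vol = n_vol, n_streamlines = n_str,
                 n_iso = n_iso, grid_shape = gs),
            class = "commit_operator")
}

#' Fit streamline and isotropic signal fractions by non-negative least squares
#'
#' Solves min ||A x - y||_2 subject to x >= 0 over the stacked
#' streamline-weight and per-voxel isotropic-fraction vector, using the
#' Lawson-Hanson active-set algorithm. The fit is deterministic for fixed
#' inputs; rank-deficient operators still return a (possibly non-unique)
#' minimiser, with a warning.
#'
#' @param operator a `commit_operator` from [build_operator()].
#' @param signal numeric matrix n_vox x n_vol (or vector of that length),
#'   as produced by [gen_dwi_signal()].
#' @return List of class `streamline_weights`: `x` (per-streamline
#'   weights, signal-fraction units), `iso` (n_vox x n_iso matrix) and
#'   `residual_norm`.
#' @export
fit_commit <- function(operator, signal) {
  y <- as.numeric(signal)
  if (length(y) != nrow(operator$A))
    stop("signal length does not match operator rows")
  if (qr(operator$A)$rank < ncol(operator$A))
    warning("rank-deficient operator: weights may not be unique")
  sol <- pracma::lsqnonneg(operator$A, y)
  x <- sol$x
  n_str <- operator$n_streamlines
  iso <- matrix(x[(n_str + 1L):length(x)], operator$n_vox, operator$n_iso)
  structure(list(
    x = if (n_str > 0) x[seq_len(n_str)] else numeric(0),
    iso = iso,
    residual_norm = sqrt(sum((operator$A %*% x - y)^2))
  ), class = "streamline_weights")
}
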