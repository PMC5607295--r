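# System-matrix construction and inversion: maps the nine pair intensities to
# the nine elements of the sample's linear Mueller matrix.

.MCOLS <- c("m11", "m12", "m13", "m21", "m22", "m23", "m31", "m32", "m33")

#' Build the 9x9 system matrix from the probe's channel Stokes vectors
#'
#' Row for pair (illuminate i, collect c) is the Kronecker product
#' `kron(c(I_c, Q_c, -U_c), c(I_i, Q_i, U_i))` of the collection analyzer
#' triplet (with the reflected-frame U sign flip) and the illumination exit
#' triplet. The factor 1/2 from the analyzer row is not folded into Z; it is
#' carried by the factor 2 in [reconstruct()]. Rows follow the fixed pair
#' scheme; columns are the row-major sample elements `m11, m12, ..., m33`.
#'
#' @param probe A `probe_model` whose six channels carry normalized exit
#'   Stokes vectors.
#' @return An object of class `system_matrix`: list with the 9x9 matrix `z`,
#'   `condition_number`, `singular_values` and `pairs`.
#' @export
#' @examples
#' z <- build_system_matrix(ideal_probe())
#' z$z["H1H2", ]
build_system_matrix <- function(probe) {
  stopifnot(inherits(probe, "probe_model"))
  missing <- setdiff(.CHANNEL_LABELS, names(probe$channels))
  if (length(missing) > 0) {
    stop("probe is missing channels: ", paste(missing, collapse = ", "))
  }
  tab <- pair_scheme()
  z <- t(vapply(seq_len(nrow(tab)), function(i) {
    esc <- probe$channels[[tab$collect[i]]]$exit_stokes
    esi <- probe$channels[[tab$illum[i]]]$exit_stokes
    kronecker(c(esc[1], esc[2], -esc[3]), esi)
  }, numeric(9)))
  dimnames(z) <- list(tab$pair, .MCOLS)
  sv <- svd(z, nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  structure(list(z = z, condition_number = cond, singular_values = sv,
                 pairs = tab$pair),
            class = "system_matrix")
}

#' Conditioning diagnostics for a system matrix
#'
#' @param z A `system_matrix`.
#' @param threshold Condition number above which the inversion is flagged as
#'   unreliable (default `1e6`, a double-precision safety margin).
#' @return List with `condition_number`, `singular_values`, `rank` and the
#'   logical `warn`.
#' @export
condition_report <- function(z, threshold = 1e6) {
  stopifnot(inherits(z, "system_matrix"))
  sv <- z$singular_values
  rank <- sum(sv > max(sv) * 1e-12)
  warn <- !is.finite(z$condition_number) || z$condition_number > threshold
  list(condition_number = z$condition_number,
       singular_values = sv,
       rank = rank,
       warn = warn)
}

.coeff_vector <- function(coeffs, pairs) {
  if (is.null(coeffs)) return(stats::setNames(rep(1, length(pairs)), pairs))
  if (inherits(coeffs, "calibration_result")) coeffs <- coeffs$c
  coeffs <- unlist(coeffs)
  if (!is.null(names(coeffs))) {
    if (!setequal(names(coeffs), pairs)) {
      stop("coefficient names do not match the pair scheme")
    }
    coeffs <- coeffs[pairs]
  } else if (length(coeffs) != length(pairs)) {
    stop("need one coefficient per measurement pair")
  } else {
    names(coeffs) <- pairs
  }
  coeffs
}

#' Reconstruct a sample Mueller matrix from nine intensities
#'
#' Solves `y = (1/2) Z m` for the row-major element vector `m`, i.e.
#' `m = 2 Z^-1 (c * y)` with optional per-pair calibration coefficients `c`.
#' The solve is by least squares (QR), which for the well-posed nine-row
#' scheme equals the explicit inverse but also supports future redundant
#' schemes.
#'
#' @param meas Named intensity vector covering exactly the nine scheme pairs
#'   (order free), as produced by [simulate_measurement_set()] or
#'   [read_measurement_set()].
#' @param z A `system_matrix`.
#' @param coeffs Optional calibration coefficients: a `calibration_result`,
#'   a named vector, or `NULL` for unit coefficients.
#' @param warn_condition Condition-number threshold passed to
#'   [condition_report()].
#' @return Object of class `reconstruction`: list with `m` (raw scale),
#'   `m_normalized` (`m / m11` when `m11 != 0`) and the solver `residual`.
#' @export
#' @examples
#' probe <- ideal_probe()
#' z <- build_system_matrix(probe)
#' ms <- simulate_measurement_set(probe, diag(c(1, 1, -1)))
#' reconstruct(ms, z)$m
reconstruct <- function(meas, z, coeffs = NULL, warn_condition = 1e6) {
  stopifnot(inherits(z, "system_matrix"))
  meas <- unlist(meas)
  if (is.null(names(meas)) || !setequal(names(meas), z$pairs)) {
    stop("measurement set must cover exactly the nine scheme pairs")
  }
  y <- meas[z$pairs]
  cv <- .coeff_vector(coeffs, z$pairs)
  rep_cond <- condition_report(z, warn_condition)
  if (rep_cond$rank < ncol(z$z)) stop("system matrix is singular")
  if (rep_cond$warn) {
    warning(sprintf("system matrix is ill-conditioned (kappa = %.3g)",
                    z$condition_number))
  }
  rhs <- cv * y
  qrz <- qr(z$z)
  mvec <- 2 * qr.coef(qrz, rhs)
  residual <- sqrt(sum((0.5 * drop(z$z %*% mvec) - rhs)^2))
  m <- matrix(mvec, 3, 3, byrow = TRUE)
  m_norm <- if (m[1, 1] != 0) m / m[1, 1] else m
  structure(list(m = m, m_normalized = m_norm, residual = residual),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> residual", format(x$residual, digits = 3), "\n")
  cat("m (raw):\n")
  print(round(x$m, 4))
  invisible(x)
}
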