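# 3x3 polar decomposition in the Lu-Chipman lineage, restricted to the
# linear block: M = M_delta . M_R . M_D (depolariser after retarder after
# diattenuator), with the reflection-geometry physical-retardance
# correction delta_phys = 180 - delta_meas.

#' Diattenuation of a linear Mueller matrix
#'
#' `sqrt(m12^2 + m13^2) / m11`: the polarisation dependence of the first-row
#' transmittance.
#'
#' @param m 3x3 linear Mueller matrix with `m11 > 0`.
#' @return Diattenuation in `[0, 1]`.
#' @export
#' @examples
#' diattenuation(diag(3))                         # 0
#' diattenuation(linear_polariser_mueller(30)[1:3, 1:3])  # 1
diattenuation <- function(m) {
  .check_mueller(m, 3L)
  if (m[1, 1] <= 0) stop("`m11` must be positive")
  sqrt(m[1, 2]^2 + m[1, 3]^2) / m[1, 1]
}

#' 3x3 linear retarder factor
#'
#' The retarder block used for recomposition:
#' `[[1,0,0],[0, c^2 + s^2 k, s c (1 - k)],[0, s c (1 - k), s^2 + c^2 k]]`
#' with `c = cos(2 axis)`, `s = sin(2 axis)`, `k = cos(delta)`. Axes `0` and
#' `90` degrees give the same block — the inherent 90-degree axis degeneracy
#' of linear-only polarimetry.
#'
#' @param axis Fast-axis angle in degrees.
#' @param delta Retardance in degrees.
#' @return 3x3 matrix.
#' @export
retarder_block <- function(axis, delta) {
  cc <- cosd(2 * axis)
  ss <- sind(2 * axis)
  k <- cosd(delta)
  matrix(c(1, 0, 0,
           0, cc^2 + ss^2 * k, ss * cc * (1 - k),
           0, ss * cc * (1 - k), ss^2 + cc^2 * k), 3, 3, byrow = TRUE)
}

#' Physical retardance in reflection geometry
#'
#' Reflected light undergoes a helicity flip, so the retardance reported by
#' decomposition of a reflection-mode measurement combines the physical
#' (round-trip) retardance with a geometrical contribution; for a retarder
#' with fast or slow axis vertical or horizontal the two are related by
#' `delta_phys = 180 - delta_meas`. For oblique axes this rule is not
#' guaranteed and the value should be read as a convention.
#'
#' @param delta_meas Measured retardance in degrees, in `[0, 180]`.
#' @return Physical retardance `180 - delta_meas` in degrees.
#' @export
#' @examples
#' physical_retardance(120)  # 60
physical_retardance <- function(delta_meas) {
  if (!is.numeric(delta_meas) || any(delta_meas < 0 | delta_meas > 180)) {
    stop("`delta_meas` must lie in [0, 180] degrees")
  }
  180 - delta_meas
}

#' Depolarisation of a depolariser factor, in percent
#'
#' `100 * (1 - (|lambda1| + |lambda2|) / 2)` where `lambda` are the
#' eigenvalues of the lower-right 2x2 block of the depolariser factor.
#' Absolute values tolerate the sign structure of reflection-mode matrices.
#'
#' @param m_delta 3x3 depolariser factor (first row `c(1, 0, 0)` to
#'   tolerance `1e-6`).
#' @return Depolarisation percentage.
#' @export
#' @examples
#' depolarisation_percent(diag(c(1, 0.5, 0.62)))  # 44
depolarisation_percent <- function(m_delta) {
  .check_mueller(m_delta, 3L, "m_delta")
  if (max(abs(m_delta[1, ] - c(1, 0, 0))) > 1e-6) {
    stop("`m_delta` is not a depolariser factor (first row must be [1, 0, 0])")
  }
  ev <- eigen(m_delta[2:3, 2:3], only.values = TRUE)$values
  100 * (1 - mean(Mod(ev)))
}

# Moore-Penrose pseudo-inverse via SVD (used for the singular retarder block
# at delta ~ 90 degrees).
.pinv <- function(x, tol = 1e-12) {
  s <- svd(x)
  pos <- s$d > tol * max(s$d, 1)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

.clamp1 <- function(x) max(-1, min(1, x))

# Factor the 2x2 (Q,U) block of M' = M_delta . M_R as B = diag(a, b) . R2
# with R2 the retarder block. Returns NULL when the block is inconsistent
# with that model — off-diagonal product <= 0, or implied depolarisation
# factors outside (0, 1] (the model is exactly identified, so it would fit
# measurement noise with unphysical factors) — in which case the caller
# falls back to the trace-based formulas.
.solve_retarder_depol <- function(B, tol) {
  if (B[1, 2] * B[2, 1] <= tol) return(NULL)
  r <- B[1, 2] / B[2, 1]                    # = a / b
  P <- B[1, 1] + r * B[2, 2]                # = a (1 + k)
  Q <- sqrt((B[1, 1] - r * B[2, 2])^2 + 4 * B[1, 2]^2)  # = a (1 - k)
  if (P + Q <= 0) return(NULL)
  k <- (P - Q) / (P + Q)
  a <- (P + Q) / 2
  b <- a / r
  if (a <= 0 || b <= 0 || a > 1 + 1e-6 || b > 1 + 1e-6) return(NULL)
  axis <- 0.25 * atan2d(2 * B[1, 2], B[1, 1] - r * B[2, 2])
  list(k = .clamp1(k), clamp = abs(k) - 1, axis = axis, factors = c(a, b))
}

#' Polar decomposition of a 3x3 linear Mueller matrix
#'
#' Factors `m = M_delta . M_R . M_D`: the diattenuator `M_D` is built from
#' the first row; the retarder parameters are extracted from
#' `M' = m . M_D^-1`; the depolariser is `M_delta = M' . M_R^-1` (with a
#' pseudo-inverse plus symmetrization of the 2x2 block when the retarder
#' block is singular, i.e. retardance within `1e-8` of 90 degrees).
#'
#' Retardance and axis come from an exact factorization of the 2x2 (Q,U)
#' block as `diag(a, b) . R(axis, delta)` whenever the block is consistent
#' with a diagonal depolariser following a retarder (off-diagonal product
#' positive); this recovers generator parameters to solver precision even
#' under strong depolarisation. For blocks outside that family (noisy or
#' strongly non-reciprocal measurements) the trace-based estimates
#' `delta = arccos(sqrt((m'22 + m'33)^2 + (m'32 - m'23)^2) - 1)` and
#' `axis = atan2(m'23 + m'32, m'22 - m'33) / 4` are used. A diagonal block
#' is degenerate (a cardinal-axis retarder and a diagonal depolariser are
#' indistinguishable in 3x3): when `m'22` is 1 the diagonal is read as a
#' pure retarder, otherwise as a pure depolariser with retardance 0 or 180
#' degrees.
#'
#' The axis is reported in `[0, 90)` degrees and is always 90-degree
#' ambiguous in linear-only polarimetry (`axis_ambiguous` stays `TRUE`).
#'
#' @param m 3x3 linear Mueller matrix with `m11 > 0` and diattenuation < 1.
#' @return Object of class `decomposition`: list with `delta_meas_deg`,
#'   `delta_phys_deg`, `axis_deg`, `axis_ambiguous`, `depolarisation_pct`,
#'   `diattenuation`, `factors` (list `m_d`, `m_r`, `m_delta` on the raw
#'   input scale) and `diagnostics` (`branch`, `clamped`).
#' @export
#' @examples
#' polar_decompose(diag(c(1, 1, -0.5)))$delta_meas_deg  # 120
polar_decompose <- function(m) {
  .check_mueller(m, 3L)
  if (m[1, 1] <= 0) stop("`m11` must be positive")
  d <- diattenuation(m)
  if (d >= 1) stop("diattenuation >= 1: matrix is not decomposable")

  mn <- m / m[1, 1]
  dv <- mn[1, 2:3]
  if (d > 1e-14) {
    dh <- dv / d
    md2 <- sqrt(1 - d^2) * diag(2) + (1 - sqrt(1 - d^2)) * (dh %o% dh)
    m_d <- rbind(c(1, dv), cbind(dv, md2))
  } else {
    m_d <- diag(3)
  }
  mp <- mn %*% solve(m_d)
  B <- mp[2:3, 2:3]

  scale2 <- max(abs(B), 1e-30)^2
  clamped <- 0
  sol <- .solve_retarder_depol(B, tol = 1e-12 * scale2)
  if (!is.null(sol)) {
    branch <- "exact"
    k <- sol$k
    clamped <- max(0, sol$clamp)
    delta <- acosd(k)
    axis <- sol$axis
  } else if (max(abs(B[1, 2]), abs(B[2, 1])) < 1e-9 * sqrt(scale2)) {
    # Degenerate diagonal block: cardinal-axis retarder vs diagonal
    # depolariser. Read as a retarder when Q is fully preserved, as a pure
    # depolariser (delta 0 or 180) otherwise.
    if (abs(B[1, 1]) >= 1 - 1e-9) {
      branch <- "diagonal-retarder"
      k <- .clamp1(B[2, 2] / B[1, 1])
      clamped <- max(0, abs(B[2, 2] / B[1, 1]) - 1)
      delta <- acosd(k)
    } else {
      branch <- "diagonal-depolariser"
      delta <- if (B[2, 2] >= 0) 0 else 180
    }
    axis <- 0
  } else {
    branch <- "trace-fallback"
    arg <- sqrt((B[1, 1] + B[2, 2])^2 + (B[2, 1] - B[1, 2])^2) - 1
    clamped <- max(0, abs(arg) - 1)
    delta <- acosd(.clamp1(arg))
    axis <- 0.25 * atan2d(B[1, 2] + B[2, 1], B[1, 1] - B[2, 2])
  }
  if (clamped > 1e-6) {
    warning(sprintf("arccos argument clamped by %.3g (noisy matrix?)",
                    clamped))
  }
  axis <- axis %% 90

  m_r <- retarder_block(axis, delta)
  rb <- m_r[2:3, 2:3]
  if (abs(cosd(delta)) < 1e-8) {          # det(rb) = cos(delta) ~ 0
    rb_inv <- .pinv(rb)
    m_delta <- mp %*% rbind(c(1, 0, 0), cbind(0, rb_inv))
    m_delta[2:3, 2:3] <- (m_delta[2:3, 2:3] + t(m_delta[2:3, 2:3])) / 2
  } else {
    m_delta <- mp %*% rbind(c(1, 0, 0), cbind(0, solve(rb)))
  }
  m_delta[1, 2:3] <- 0                    # exact by construction; tidy fp dust

  depol <- 100 * (1 - mean(Mod(eigen(m_delta[2:3, 2:3],
                                     only.values = TRUE)$values)))

  structure(list(delta_meas_deg = delta,
                 delta_phys_deg = physical_retardance(delta),
                 axis_deg = axis,
                 axis_ambiguous = TRUE,
                 depolarisation_pct = depol,
                 diattenuation = d,
                 factors = list(m_d = m[1, 1] * m_d,
                                m_r = m_r,
                                m_delta = m_delta),
                 diagnostics = list(branch = branch, clamped = clamped)),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(paste0("<decomposition> delta_meas %.2f deg (phys %.2f), ",
                     "axis %.2f deg (mod 90), depol %.1f%%, diatten %.3f\n"),
              x$delta_meas_deg, x$delta_phys_deg, x$axis_deg,
              x$depolarisation_pct, x$diattenuation))
  invisible(x)
}
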