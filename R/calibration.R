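# Mirror-polariser calibration: simulate the polariser double-pass reference
# targets and fit the nine per-pair coupling coefficients by nonlinear
# regression on the normalized reconstructed Mueller matrices.

#' Reference target for a polariser double pass at angle theta
#'
#' The known "sample" seen by the probe during calibration: light traverses
#' an external linear polariser at `theta`, reflects off an ideal mirror, and
#' traverses the polariser again at `180 - theta` (frame reversal). Composed
#' in full 4x4 by default; independently measured polariser matrices may be
#' substituted (4x4, or 3x3 which is sufficient for polarisers since an
#' ideal linear polariser has no circular coupling).
#'
#' @param theta External polariser angle in degrees.
#' @param m_polariser Optional measured Mueller matrix of the polariser at
#'   `theta` (4x4 or 3x3).
#' @param m_polariser_back Optional measured matrix of the second pass at
#'   `180 - theta`; defaults to `m_polariser` mirrored conventionally only
#'   when both are ideal (i.e. must be supplied alongside `m_polariser`).
#' @return 3x3 linear Mueller matrix of the double pass.
#' @export
#' @examples
#' reference_target_mueller(45)  # 0.5 * [[1,0,1],[0,0,0],[-1,0,-1]]
reference_target_mueller <- function(theta, m_polariser = NULL,
                                     m_polariser_back = NULL) {
  if (is.null(m_polariser)) {
    return(linear_submatrix(double_pass("polariser", theta)))
  }
  if (is.null(m_polariser_back)) {
    stop("supply `m_polariser_back` (the 180 - theta pass) with `m_polariser`")
  }
  n <- nrow(m_polariser)
  stopifnot(all(dim(m_polariser) == n), all(dim(m_polariser_back) == n),
            n %in% c(3L, 4L))
  if (n == 4L) {
    linear_submatrix(m_polariser_back %*% mirror_mueller() %*% m_polariser)
  } else {
    m_polariser_back %*% diag(c(1, 1, -1)) %*% m_polariser
  }
}

#' Simulate a calibration session
#'
#' For each external polariser angle, the sample is the corresponding
#' double-pass reference target and the nine pair intensities are generated
#' through the forward model with the probe's true couplings.
#'
#' @param probe A `probe_model`.
#' @param angles External polariser angles in degrees (default `c(0, 30, 60)`).
#' @param noise Optional [noise_model()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `angle_deg`, `pair`, `intensity`
#'   (one row per angle and pair).
#' @export
#' @examples
#' simulate_calibration_session(ideal_probe())
simulate_calibration_session <- function(probe, angles = c(0, 30, 60),
                                         noise = NULL, seed = NULL) {
  stopifnot(inherits(probe, "probe_model"), length(angles) >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(angles, function(a) {
    ms <- simulate_measurement_set(probe, reference_target_mueller(a),
                                   noise = noise)
    data.frame(angle_deg = a, pair = names(ms), intensity = unname(ms),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.validate_session <- function(session) {
  stopifnot(is.data.frame(session),
            all(c("angle_deg", "pair", "intensity") %in% names(session)))
  angles <- sort(unique(session$angle_deg))
  if (length(angles) < 2) {
    stop("calibration needs at least 2 distinct polariser angles")
  }
  for (a in angles) {
    pairs_a <- session$pair[session$angle_deg == a]
    missing <- setdiff(pair_labels(), pairs_a)
    if (length(missing) > 0) {
      stop(sprintf("angle %g: missing pair(s) %s", a,
                   paste(missing, collapse = ", ")))
    }
    if (anyDuplicated(pairs_a)) {
      stop(sprintf("angle %g: duplicated pair rows", a))
    }
  }
  if (any(session$intensity < 0)) stop("intensities must be non-negative")
  angles
}

# Closed-form warm start: at the optimum, diag(c) y_theta is proportional
# (per angle) to the model intensities (1/2) Z t_theta, so
# log c_i - log lambda_theta = log y_model - log y_meas is linear least
# squares in (log c, log lambda). Zero intensities are excluded; the flat
# overall-scale direction is pinned by dropping one lambda.
.warm_start <- function(z, ys, Ts, bounds) {
  rows_x <- list()
  rhs <- numeric(0)
  n_ang <- length(ys)
  for (a in seq_len(n_ang)) {
    y_model <- 0.5 * drop(z %*% Ts[[a]])
    y_meas <- ys[[a]]
    keep <- which(y_model > 1e-12 & y_meas > 1e-12)
    for (i in keep) {
      x <- numeric(9 + n_ang - 1)
      x[i] <- 1
      if (a < n_ang) x[9 + a] <- -1
      rows_x[[length(rows_x) + 1]] <- x
      rhs <- c(rhs, log(y_model[i]) - log(y_meas[i]))
    }
  }
  X <- do.call(rbind, rows_x)
  beta <- tryCatch(qr.coef(qr(X), rhs), error = function(e) NULL)
  if (is.null(beta)) return(rep(1, 9))
  lc <- beta[1:9]
  lc[is.na(lc)] <- 0
  pmin(pmax(exp(lc), bounds[1]), bounds[2])
}

# Smoothed-L1 objective and its analytic gradient. For each angle:
#   u = A c  with  A = 2 * Zinv %*% diag(y)   (u is the row-major m vector),
#   v = u / u[1]  (normalization by m11),  d = v - t  (normalized target),
#   F = mean over angles and elements of sqrt(d^2 + eps^2).
.calib_objective <- function(As, Ts, eps) {
  n_terms <- length(As) * 9
  fn <- function(cc) {
    total <- 0
    for (i in seq_along(As)) {
      u <- drop(As[[i]] %*% cc)
      d <- u / u[1] - Ts[[i]]
      total <- total + sum(sqrt(d^2 + eps^2))
    }
    total / n_terms
  }
  gr <- function(cc) {
    g <- numeric(length(cc))
    for (i in seq_along(As)) {
      A <- As[[i]]
      u <- drop(A %*% cc)
      v <- u / u[1]
      d <- v - Ts[[i]]
      w <- d / sqrt(d^2 + eps^2)
      # dF/dc_j = sum_i w_i (A_ij u1 - u_i A_1j) / u1^2
      g <- g + (drop(crossprod(A, w)) - sum(w * v) * A[1, ]) / u[1]
    }
    g / n_terms
  }
  list(fn = fn, gr = gr)
}

#' Fit the nine calibration coefficients
#'
#' Finds coefficients `c` minimizing the mean absolute difference between the
#' m11-normalized Mueller matrix reconstructed from the (coefficient-scaled)
#' session intensities and the m11-normalized reference target, averaged
#' over angles and the nine elements. The objective is invariant under a
#' global rescaling of `c` (normalization removes overall scale), so the
#' returned coefficients are gauge-fixed to `mean(c) = 1`.
#'
#' The minimization uses a smoothed absolute value `sqrt(d^2 + eps^2)` with
#' analytic gradient under `L-BFGS-B` bounds. The start point is a
#' closed-form log-linear intensity match (each coefficient-scaled intensity
#' proportional, per angle, to the intensity the forward model predicts for
#' the target), which for a noiseless session already sits at the global
#' optimum; for an ideal session both stages leave `c = 1`.
#'
#' @param session Calibration table (`angle_deg`, `pair`, `intensity`) from
#'   [simulate_calibration_session()] or [read_calibration_session()];
#'   at least two distinct angles.
#' @param z A `system_matrix`.
#' @param targets Optional named list mapping each angle (as character) to
#'   its 3x3 target matrix; defaults to ideal [reference_target_mueller()].
#' @param options List of optimizer options: `bounds` (default
#'   `c(0.1, 10)`), `eps` (default `1e-9`), `maxit` (default `10000`).
#' @return Object of class `calibration_result`: list with `c` (named,
#'   gauge-fixed), `gauge`, `objective_value` (exact mean absolute element
#'   difference at the optimum) and `converged`.
#' @export
#' @examples
#' probe <- ideal_probe()
#' z <- build_system_matrix(probe)
#' fit <- fit_coefficients(simulate_calibration_session(probe), z)
#' round(fit$c, 6)  # all 1
fit_coefficients <- function(session, z, targets = NULL, options = list()) {
  stopifnot(inherits(z, "system_matrix"))
  angles <- .validate_session(session)
  opts <- utils::modifyList(list(bounds = c(0.1, 10), eps = 1e-9,
                                 maxit = 10000L), options)
  zinv <- solve(z$z)

  As <- list()
  Ts <- list()
  ys <- list()
  for (a in angles) {
    rows <- session[session$angle_deg == a, ]
    y <- stats::setNames(rows$intensity, rows$pair)[z$pairs]
    tgt <- if (!is.null(targets)) targets[[as.character(a)]] else
      reference_target_mueller(a)
    if (is.null(tgt)) stop("no target supplied for angle ", a)
    if (tgt[1, 1] <= 0) stop("target m11 must be positive (angle ", a, ")")
    As[[length(As) + 1]] <- 2 * sweep(zinv, 2, y, "*")
    Ts[[length(Ts) + 1]] <- as.vector(t(tgt / tgt[1, 1]))
    ys[[length(ys) + 1]] <- y
  }

  start <- .warm_start(z$z, ys, Ts, opts$bounds)
  obj <- .calib_objective(As, Ts, opts$eps)
  res <- stats::optim(start, obj$fn, obj$gr, method = "L-BFGS-B",
                      lower = opts$bounds[1], upper = opts$bounds[2],
                      control = list(maxit = opts$maxit, factr = 10,
                                     pgtol = 0))
  cc <- res$par / mean(res$par)
  names(cc) <- z$pairs
  exact <- mean(vapply(seq_along(As), function(i) {
    u <- drop(As[[i]] %*% cc)
    mean(abs(u / u[1] - Ts[[i]]))
  }, numeric(1)))
  structure(list(c = cc,
                 gauge = "mean(c) = 1",
                 objective_value = exact,
                 converged = res$convergence == 0,
                 optim = list(value = res$value, counts = res$counts,
                              message = res$message)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> gauge", x$gauge,
      "objective", format(x$objective_value, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$c, 4))
  invisible(x)
}
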