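# Virtual probe: six micro-polariser terminated fibre channels, exit Stokes
# vectors, analyzer rows with the collection-side U sign flip, per-pair
# channel couplings, intensity simulation, footprint geometry and synthetic
# tissue fixtures.

.CHANNEL_LABELS <- c("H1", "H2", "V1", "V2", "B1", "B2")
.NOMINAL_ANGLES <- c(H1 = 0, H2 = 0, V1 = 90, V2 = 90, B1 = 135, B2 = 135)

.PAIR_TABLE <- data.frame(
  pair = c("H1H2", "H1V2", "H1B1", "V2H1", "V2V1", "V2B1",
           "B1H1", "B1V2", "B1B2"),
  illum = c("H1", "H1", "H1", "V2", "V2", "V2", "B1", "B1", "B1"),
  collect = c("H2", "V2", "B1", "H1", "V1", "B1", "H1", "V2", "B2"),
  stringsAsFactors = FALSE
)

# Coupling spread representative of a hand-assembled first prototype (the
# reciprocal of a measured per-pair calibration coefficient set with ~30%
# scatter, normalized to mean 1). Used as the default "true" couplings that a
# calibration run is expected to undo.
.PROTOTYPE_COEFFS <- c(H1H2 = 1.18, H1V2 = 0.83, H1B1 = 0.74,
                       V2H1 = 0.70, V2V1 = 1.21, V2B1 = 1.51,
                       B1H1 = 1.24, B1V2 = 1.17, B1B2 = 1.42)

#' The fixed nine-pair measurement scheme
#'
#' Each row names one intensity measurement: the first channel illuminates,
#' the second collects. The row order is the canonical ordering used by the
#' system matrix, measurement files and calibration coefficients.
#'
#' @return A data frame with columns `pair`, `illum`, `collect`.
#' @export
#' @examples
#' pair_scheme()
pair_scheme <- function() .PAIR_TABLE

#' @rdname pair_scheme
#' @export
pair_labels <- function() .PAIR_TABLE$pair

.default_geometry <- function() {
  list(core_um = 400, na = 0.39, pitch_um = 1000, medium_ri = 1.0)
}

#' Build a virtual probe model
#'
#' Constructs the six channels from a configuration list. For every channel
#' without a user-supplied `exit_stokes`, the exit state is computed by
#' passing the (possibly partially polarised) source through the channel's
#' ideal micro-polariser and normalizing the intensity to 1; the discarded
#' pre-normalization intensity becomes an illumination weight that is
#' absorbed into the per-pair couplings (a partially polarised source changes
#' how much light each channel emits, not its exit polarisation).
#'
#' @param config A list with optional entries:
#'   \describe{
#'     \item{channels}{named list (labels `H1,H2,V1,V2,B1,B2`) of lists with
#'       `polariser_angle_deg` and/or `exit_stokes` (length-3 `c(I, Q, U)`).}
#'     \item{source}{list with `dop` (default 0.15) and `axis_deg` (default 0).}
#'     \item{gains}{named numeric: either the 9 pair labels or the 6 fibre
#'       labels (expanded to pairs by products). Default: a representative
#'       prototype coupling spread; use [ideal_probe()] for unit couplings.}
#'     \item{geometry}{list with `core_um`, `na`, `pitch_um`, `medium_ri`.}
#'     \item{angle_jitter_deg}{half-width of a uniform perturbation applied to
#'       nominal micro-polariser angles (orientation accuracy); default 0.}
#'     \item{seed}{integer seed used when `angle_jitter_deg > 0`.}
#'   }
#' @return An object of class `probe_model`.
#' @seealso [ideal_probe()], [simulate_measurement_set()]
#' @export
#' @examples
#' p <- build_probe()
#' p$channels$H1$exit_stokes
build_probe <- function(config = list()) {
  stopifnot(is.list(config))
  known <- c("channels", "source", "gains", "geometry",
             "angle_jitter_deg", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop("unknown probe config keys: ", paste(extra, collapse = ", "))
  }

  source <- config$source %||% list()
  dop <- source$dop %||% 0.15
  src_axis <- source$axis_deg %||% 0
  src <- stokes_linear_state(src_axis, dop = dop, intensity = 1)

  jitter <- config$angle_jitter_deg %||% 0
  if (jitter > 0 && !is.null(config$seed)) set.seed(config$seed)

  channels <- list()
  weights <- numeric(0)
  for (lab in .CHANNEL_LABELS) {
    spec <- config$channels[[lab]] %||% list()
    angle <- canonical_axis(spec$polariser_angle_deg %||% .NOMINAL_ANGLES[[lab]])
    if (jitter > 0) angle <- angle + stats::runif(1, -jitter, jitter)
    if (!is.null(spec$exit_stokes)) {
      es <- as.numeric(spec$exit_stokes)
      if (length(es) != 3L || es[1] <= 0) {
        stop(sprintf("channel %s: `exit_stokes` must be c(I, Q, U) with I > 0",
                     lab))
      }
      w <- es[1]
      es <- es / es[1]
    } else {
      out <- apply_mueller(linear_polariser_mueller(angle), src)
      if (out[1] <= 0) {
        stop(sprintf("channel %s: source state is extinguished (I <= 0)", lab))
      }
      w <- out[1]
      es <- (out / out[1])[1:3]
    }
    channels[[lab]] <- list(label = lab, polariser_angle = angle,
                            exit_stokes = es)
    weights[[lab]] <- w
  }
  weights <- weights / mean(weights)

  gains <- .expand_gains(config$gains %||% (1 / .PROTOTYPE_COEFFS))
  couplings <- gains * weights[.PAIR_TABLE$illum]
  names(couplings) <- .PAIR_TABLE$pair

  geometry <- utils::modifyList(.default_geometry(),
                                as.list(config$geometry %||% list()))

  structure(list(channels = channels,
                 source = list(dop = dop, axis_deg = src_axis),
                 couplings = couplings,
                 gains_config = gains,
                 illumination_weights = weights,
                 geometry = geometry),
            class = "probe_model")
}

# Accept per-pair (9) or per-fibre (6) gains; per-fibre gains expand to pairs
# as the product of the illumination and collection fibre gains.
.expand_gains <- function(gains) {
  gains <- unlist(gains)
  if (!is.numeric(gains) || is.null(names(gains))) {
    stop("`gains` must be a named numeric vector or list")
  }
  if (any(gains <= 0)) stop("gains must be positive")
  if (setequal(names(gains), .PAIR_TABLE$pair)) {
    return(gains[.PAIR_TABLE$pair])
  }
  if (setequal(names(gains), .CHANNEL_LABELS)) {
    out <- gains[.PAIR_TABLE$illum] * gains[.PAIR_TABLE$collect]
    names(out) <- .PAIR_TABLE$pair
    return(out)
  }
  stop("`gains` must name either the 9 measurement pairs or the 6 fibres")
}

#' Ideal reference probe
#'
#' Exact cardinal micro-polariser angles, an unpolarised source and unit
#' per-pair couplings: the instrument for which uncalibrated reconstruction
#' is already exact.
#'
#' @return A `probe_model`.
#' @export
ideal_probe <- function() {
  build_probe(list(source = list(dop = 0, axis_deg = 0),
                   gains = stats::setNames(rep(1, 9), .PAIR_TABLE$pair)))
}

#' @export
print.probe_model <- function(x, ...) {
  cat("<probe_model> 6 channels, source DOP", x$source$dop, "\n")
  for (ch in x$channels) {
    cat(sprintf("  %s: angle %7.3f deg, exit [1, %+.4f, %+.4f]\n",
                ch$label, ch$polariser_angle,
                ch$exit_stokes[2], ch$exit_stokes[3]))
  }
  cat("  couplings:", paste(sprintf("%s=%.3f", names(x$couplings),
                                    x$couplings), collapse = " "), "\n")
  invisible(x)
}

#' Analyzer row of a collection channel
#'
#' First row of the collection micro-polariser's Mueller matrix as seen by
#' light travelling back into the fibre: `0.5 * c(I, Q, -U)` of the channel's
#' normalized exit Stokes vector. The sign of U flips because the exit state
#' is characterized for light travelling out of the probe, while collected
#' light travels in the opposite direction.
#'
#' @param channel A channel entry of a `probe_model` (or a `probe_model` plus
#'   a `label`).
#' @param label Channel label when `channel` is a `probe_model`.
#' @return Numeric length-3 analyzer row.
#' @export
#' @examples
#' analyzer_row(ideal_probe(), "B1")  # 0.5 * c(1, 0, +1)
analyzer_row <- function(channel, label = NULL) {
  if (inherits(channel, "probe_model")) {
    stopifnot(!is.null(label))
    channel <- channel$channels[[label]]
    if (is.null(channel)) stop("unknown channel label: ", label)
  }
  es <- channel$exit_stokes
  0.5 * c(es[1], es[2], -es[3])
}

#' Simulation noise model
#'
#' Multiplicative Gaussian noise with relative standard deviation
#' `sigma_rel` (coefficient of variation) plus an additive Gaussian dark
#' floor with standard deviation `dark` (intensity units); simulated
#' intensities are clamped at zero.
#'
#' @param sigma_rel Coefficient of variation of the multiplicative term.
#' @param dark Standard deviation of the additive dark term.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0, dark = 0) {
  stopifnot(sigma_rel >= 0, dark >= 0)
  structure(list(sigma_rel = sigma_rel, dark = dark), class = "noise_model")
}

.apply_noise <- function(intensity, noise) {
  if (is.null(noise)) return(intensity)
  stopifnot(inherits(noise, "noise_model"))
  out <- intensity * (1 + noise$sigma_rel * stats::rnorm(length(intensity))) +
    noise$dark * stats::rnorm(length(intensity))
  pmax(out, 0)
}

#' Simulate one pair intensity
#'
#' Detected intensity for one illumination/collection channel pair:
#' `gain * analyzer_row(collect) . M_sample . exit_stokes(illum)`. Only the
#' total intensity of the collected state matters, so the collection fibre's
#' own polarisation transformation drops out of the measurement.
#'
#' @param illum,collect Channel entries (see [analyzer_row()]).
#' @param sample 3x3 linear Mueller matrix of the sample (extracted from a
#'   physically composed 4x4 system).
#' @param gain Positive coupling factor for the pair.
#' @param noise Optional [noise_model()].
#' @param seed Optional integer seed (set before drawing noise).
#' @return Non-negative intensity.
#' @export
simulate_intensity <- function(illum, collect, sample, gain = 1,
                               noise = NULL, seed = NULL) {
  .check_mueller(sample, 3L, "sample")
  if (gain < 0) stop("`gain` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  raw <- gain * drop(analyzer_row(collect) %*% sample %*% illum$exit_stokes)
  max(.apply_noise(raw, noise), 0)
}

#' Simulate the full nine-pair measurement set
#'
#' Applies [simulate_intensity()] over the fixed nine-pair scheme using the
#' probe's per-pair couplings.
#'
#' @param probe A `probe_model`.
#' @param sample 3x3 linear sample Mueller matrix.
#' @param noise Optional [noise_model()].
#' @param seed Optional integer seed (set once before the nine draws).
#' @return Named numeric vector of nine intensities, ordered and named by the
#'   pair scheme.
#' @export
#' @examples
#' ms <- simulate_measurement_set(ideal_probe(), diag(c(1, 1, -1)))
#' ms["H1H2"]  # 1
simulate_measurement_set <- function(probe, sample, noise = NULL, seed = NULL) {
  stopifnot(inherits(probe, "probe_model"))
  .check_mueller(sample, 3L, "sample")
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(nrow(.PAIR_TABLE)), function(i) {
    simulate_intensity(probe$channels[[.PAIR_TABLE$illum[i]]],
                       probe$channels[[.PAIR_TABLE$collect[i]]],
                       sample,
                       gain = probe$couplings[[.PAIR_TABLE$pair[i]]],
                       noise = noise)
  }, numeric(1))
  names(out) <- .PAIR_TABLE$pair
  out
}

# Hexagonal ring positions (um) for the six channels; centre-to-centre
# distance to the ring centre equals the pitch. Illumination and collection
# labels alternate so that every scheme pair sits on adjacent or
# next-adjacent vertices.
.channel_positions <- function(pitch_um) {
  order <- c("H1", "H2", "V2", "V1", "B1", "B2")
  ang <- (seq_along(order) - 1) * 60
  pos <- cbind(x = pitch_um * cosd(ang), y = pitch_um * sind(ang))
  rownames(pos) <- order
  pos
}

# Area of intersection of two equal circles of radius r at centre distance p.
.circle_overlap <- function(r, p) {
  if (p >= 2 * r) return(0)
  if (p <= 0) return(pi * r^2)
  2 * r^2 * acos(p / (2 * r)) - (p / 2) * sqrt(4 * r^2 - p^2)
}

#' Illumination/collection footprint versus working distance
#'
#' First-order surface footprint: each channel's spot diameter grows from the
#' fibre core by twice the working distance times the tangent of the
#' acceptance half-angle `asin(NA / medium_ri)`. Pairwise overlap is the
#' circle-circle intersection area over the single-spot area at the probe's
#' channel pitch; in scattering tissue the true sampling volumes overlap
#' more than these surface contours suggest.
#'
#' @param working_distance_mm Probe-to-surface distance in mm (`>= 0`).
#' @param geometry Geometry list (`core_um`, `na`, `pitch_um`, `medium_ri`),
#'   e.g. `build_probe()$geometry`.
#' @return List with `spot_diameter_mm`, `half_angle_deg` and
#'   `pairwise_overlap_fraction` (named by the nine scheme pairs).
#' @export
#' @examples
#' footprint(1.0, ideal_probe()$geometry)
footprint <- function(working_distance_mm, geometry = .default_geometry()) {
  stopifnot(working_distance_mm >= 0)
  na_eff <- geometry$na / geometry$medium_ri
  if (!is.finite(na_eff) || na_eff <= 0 || na_eff > 1) {
    stop("NA / medium_ri must lie in (0, 1]")
  }
  half_angle <- asin(na_eff)
  spot_mm <- geometry$core_um / 1000 +
    2 * working_distance_mm * tan(half_angle)
  pos <- .channel_positions(geometry$pitch_um)
  r_um <- spot_mm * 1000 / 2
  overlap <- vapply(seq_len(nrow(.PAIR_TABLE)), function(i) {
    p <- sqrt(sum((pos[.PAIR_TABLE$illum[i], ] -
                     pos[.PAIR_TABLE$collect[i], ])^2))
    .circle_overlap(r_um, p) / (pi * r_um^2)
  }, numeric(1))
  names(overlap) <- .PAIR_TABLE$pair
  list(spot_diameter_mm = spot_mm,
       half_angle_deg = half_angle / .DEG,
       pairwise_overlap_fraction = overlap)
}

# 4x4 linear diattenuator of diattenuation d along axis theta, m11 = 1.
.diattenuator4 <- function(d, theta) {
  if (d < 0 || d >= 1) stop("diattenuation must lie in [0, 1)")
  if (d == 0) return(diag(4))
  dv <- c(d * cosd(2 * theta), d * sind(2 * theta), 0)
  dh <- dv / d
  md <- sqrt(1 - d^2) * diag(3) + (1 - sqrt(1 - d^2)) * (dh %o% dh)
  out <- rbind(c(1, dv), cbind(dv, md))
  dimnames(out) <- NULL
  out
}

#' Synthetic tissue-like linear Mueller matrix
#'
#' Composes (in full 4x4) a diagonal linear depolariser, an ideal linear
#' retarder and a weak linear diattenuator, in the order
#' `depolariser . retarder . diattenuator`, and extracts the 3x3 linear
#' block. In `"reflection"` mode the retarder is traversed twice around an
#' ideal mirror and `delta` is interpreted as the physical (round-trip)
#' retardance, i.e. each pass carries `delta / 2` — the geometry of a probe
#' facing tissue backed by the calibration mirror.
#'
#' @param delta Retardance in degrees (physical round-trip value in
#'   reflection mode).
#' @param axis Retarder fast-axis angle in degrees.
#' @param depol_factors Length-2 vector in `[0, 1]`: Q and U polarisation
#'   preservation factors of the depolariser (1 = none, 0 = complete).
#' @param diatten Diattenuation in `[0, 1)`.
#' @param diatten_axis Diattenuator axis in degrees.
#' @param mode `"transmission"` or `"reflection"`.
#' @return 3x3 matrix with attribute `truth` recording the generator
#'   parameters, for recovery tests.
#' @export
#' @examples
#' make_synthetic_tissue(60, 90, mode = "reflection")  # diag(1, 1, -0.5)
make_synthetic_tissue <- function(delta = 0, axis = 0,
                                  depol_factors = c(1, 1),
                                  diatten = 0, diatten_axis = 0,
                                  mode = c("transmission", "reflection")) {
  mode <- match.arg(mode)
  stopifnot(length(depol_factors) == 2L)
  if (any(depol_factors < 0 | depol_factors > 1)) {
    stop("`depol_factors` must lie in [0, 1]")
  }
  a <- depol_factors[1]
  b <- depol_factors[2]
  depol4 <- diag(c(1, a, b, (a + b) / 2))
  ret4 <- if (mode == "reflection") {
    double_pass("retarder", axis, delta / 2)
  } else {
    linear_retarder_mueller(axis, delta)
  }
  m4 <- depol4 %*% ret4 %*% .diattenuator4(diatten, diatten_axis)
  m <- linear_submatrix(m4)
  attr(m, "truth") <- list(delta = delta, axis = axis,
                           depol_factors = depol_factors,
                           diatten = diatten, diatten_axis = diatten_axis,
                           mode = mode)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
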