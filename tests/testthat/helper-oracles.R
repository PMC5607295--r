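# Shared fixtures and independent oracles, built in code at test time.

# Random 3x3 sample matrix (not necessarily physical; exercises linear algebra).
random_mueller3 <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  m[1, 1] <- abs(m[1, 1]) + 1
  m
}

# Random normalized exit Stokes triplet c(1, Q, U) with Q^2 + U^2 <= 1.
random_exit_stokes <- function() {
  repeat {
    qu <- stats::runif(2, -1, 1)
    if (sum(qu^2) <= 1) return(c(1, qu))
  }
}

# Probe whose six channels carry the given exit Stokes triplets.
probe_with_exits <- function(exits) {
  cfg <- list(
    channels = lapply(exits, function(e) list(exit_stokes = e)),
    source = list(dop = 0),
    gains = stats::setNames(rep(1, 9), pair_labels())
  )
  build_probe(cfg)
}

# Independent element-by-element transcription of the printed full-form
# system matrix: each row written out literally from the per-channel Stokes
# parameters, with the minus signs on every U term of the collection channel.
transcribed_system_matrix <- function(st) {
  I <- function(ch) st[[ch]][1]
  Q <- function(ch) st[[ch]][2]
  U <- function(ch) st[[ch]][3]
  row_for <- function(col, ill) {
    c(I(col) * I(ill), I(col) * Q(ill), I(col) * U(ill),
      Q(col) * I(ill), Q(col) * Q(ill), Q(col) * U(ill),
      -U(col) * I(ill), -U(col) * Q(ill), -U(col) * U(ill))
  }
  rbind(
    row_for("H2", "H1"),
    row_for("V2", "H1"),
    row_for("B1", "H1"),
    row_for("H1", "V2"),
    row_for("V1", "V2"),
    row_for("B1", "V2"),
    row_for("H1", "B1"),
    row_for("V2", "B1"),
    row_for("B2", "B1")
  )
}

# Random non-depolarising, unit-transmittance 4x4 (product of retarders):
# stands in for the collection fibre's unknown polarisation transformation.
random_nondepolarising4 <- function(n_factors = 3) {
  m <- diag(4)
  for (i in seq_len(n_factors)) {
    m <- m %*% linear_retarder_mueller(stats::runif(1, 0, 180),
                                       stats::runif(1, 0, 360))
  }
  m
}

expect_matrix_equal <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected)), tol)
}
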