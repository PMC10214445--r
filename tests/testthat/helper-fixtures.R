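# shared helpers for the test suite

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small relaxed vesicle reused across dynamics tests (built once per session)
small_vesicle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      R0 <- vesicle_radius_for(642)
      cache <<- list(ves = build_vesicle(642, R0, seed = 1), R0 = R0)
    }
    cache
  }
})

# independent re-implementation of the wrapping-state decision table,
# written as a flat rule list (oracle for the classifier)
oracle_classify <- function(f1, f2, contact2, attached, theta) {
  if (!attached) return("none")
  if (f1 >= 0.9 && f2 >= 0.9) return("F")
  if (f1 >= 0.9 && f2 >= 0.05) return("E1")
  if (f1 >= 0.9 && contact2) return("E1")
  if (f1 >= 0.9) return("D")
  if (f1 >= 0.45 && !contact2) return("B")
  if (f1 >= 0.45 && f2 >= 0.2) return("E2")
  if (f1 >= 0.45) return("E1")
  if (f1 >= 0.05 && !contact2) return("B")
  if (f1 >= 0.05 && f1 >= 0.2 && f2 >= 0.2) return("E2")
  if (f1 >= 0.05) return("C")
  if (contact2) return("A3")
  if (!is.na(theta) && theta < 30) return("A1")
  "A2"
}
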