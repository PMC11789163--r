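# Niggli cell reduction (Krivy & Gruber's algorithm with numerical
# tolerances).  Two descriptions of the same lattice -- different basis
# choices related by a unimodular transform -- share one reduced cell, which
# is what duplicate detection compares.

#' Niggli-reduced cell parameters
#'
#' Reduces a unit cell to its Niggli form, the canonical representative of
#' the lattice: all equivalent settings of one lattice map to the same
#' reduced parameters (up to the numerical tolerance).
#'
#' @param cell Length-6 (a, b, c, alpha, beta, gamma), Angstrom/degrees.
#' @param eps Relative tolerance of the reduction's comparisons.
#' @param max_iter Iteration cap.
#' @return Length-6 reduced cell parameters.
#' @export
#' @examples
#' niggli_reduce(c(4, 4, 4, 60, 60, 60))
niggli_reduce <- function(cell, eps = 1e-5, max_iter = 200L) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  A <- a * a; B <- b * b; C <- cc * cc
  xi <- 2 * b * cc * cos(al)
  eta <- 2 * a * cc * cos(be)
  zeta <- 2 * a * b * cos(ga)
  e <- eps * (a * b * cc)^(2 / 3)

  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) break
    # A1: order A <= B
    if (A > B + e || (abs(A - B) <= e && abs(xi) > abs(eta) + e)) {
      tmp <- A; A <- B; B <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
    }
    # A2: order B <= C
    if (B > C + e || (abs(B - C) <= e && abs(eta) > abs(zeta) + e)) {
      tmp <- B; B <- C; C <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      next
    }
    # A3/A4: sign convention
    l <- if (xi > e) 1L else if (xi < -e) -1L else 0L
    m <- if (eta > e) 1L else if (eta < -e) -1L else 0L
    n <- if (zeta > e) 1L else if (zeta < -e) -1L else 0L
    if (l * m * n == 1L) {
      xi <- abs(xi); eta <- abs(eta); zeta <- abs(zeta)
    } else {
      xi <- -abs(xi); eta <- -abs(eta); zeta <- -abs(zeta)
    }
    # A5
    if (abs(xi) > B + e ||
        (abs(xi - B) <= e && 2 * eta < zeta - e) ||
        (abs(xi + B) <= e && zeta < -e)) {
      s <- sign(xi)
      C <- B + C - xi * s
      eta <- eta - zeta * s
      xi <- xi - 2 * B * s
      next
    }
    # A6
    if (abs(eta) > A + e ||
        (abs(eta - A) <= e && 2 * xi < zeta - e) ||
        (abs(eta + A) <= e && zeta < -e)) {
      s <- sign(eta)
      C <- A + C - eta * s
      xi <- xi - zeta * s
      eta <- eta - 2 * A * s
      next
    }
    # A7
    if (abs(zeta) > A + e ||
        (abs(zeta - A) <= e && 2 * xi < eta - e) ||
        (abs(zeta + A) <= e && eta < -e)) {
      s <- sign(zeta)
      B <- A + B - zeta * s
      xi <- xi - eta * s
      zeta <- zeta - 2 * A * s
      next
    }
    # A8
    tot <- xi + eta + zeta + A + B
    if (tot < -e ||
        (abs(tot) <= e && 2 * (A + eta) + zeta > e)) {
      C <- A + B + C + xi + eta + zeta
      xi <- 2 * B + xi + zeta
      eta <- 2 * A + eta + zeta
      next
    }
    break
  }
  a2 <- sqrt(A); b2 <- sqrt(B); c2 <- sqrt(C)
  cal <- xi / (2 * b2 * c2)
  cbe <- eta / (2 * a2 * c2)
  cga <- zeta / (2 * a2 * b2)
  clamp1 <- function(x) max(-1, min(1, x))
  c(a2, b2, c2,
    acos(clamp1(cal)) * 180 / pi,
    acos(clamp1(cbe)) * 180 / pi,
    acos(clamp1(cga)) * 180 / pi)
}
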