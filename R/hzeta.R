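# Hurwitz (generalized) zeta function zeta(a, q) = sum_{j>=0} (q + j)^(-a),
# a > 1, q > 0, by Euler-Maclaurin summation: explicit head plus tail
# corrections. Accurate to ~1e-13 for the a in (1, 20] used here.
# Vectorized over q.
hzeta <- function(a, q) {
  stopifnot(a > 1, all(q > 0))
  nhead <- 12L
  j <- 0:(nhead - 1L)
  head_sum <- vapply(q, function(qi) sum((qi + j)^(-a)), numeric(1))
  Q <- q + nhead
  head_sum +
    Q^(1 - a) / (a - 1) +
    0.5 * Q^(-a) +
    a * Q^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * Q^(-a - 3) / 720 +
    a * (a + 1) * (a + 2) * (a + 3) * (a + 4) * Q^(-a - 5) / 30240
}

# d/da log zeta(a, q) = zeta'(a, q) / zeta(a, q), central difference.
hzeta_dlog <- function(a, q, h = 1e-6) {
  (log(hzeta(a + h, q)) - log(hzeta(a - h, q))) / (2 * h)
}
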