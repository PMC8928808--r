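# Shared fixtures: analytic contours and cohort draws, built in code.

circle_contour <- function(r, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nuclear_contour(r * cos(th), r * sin(th))
}

# draw n rupture-site counts under the independence model P(N >= k) = p^k
draw_null_sites <- function(n, p) {
  b <- matrix(runif(3 * n) < p, nrow = n)
  as.integer(b[, 1] + (b[, 1] & b[, 2]) + (b[, 1] & b[, 2] & b[, 3]))
}

default_fit <- function() sigmoid_fit(50, 4, 8, mode = "full")
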