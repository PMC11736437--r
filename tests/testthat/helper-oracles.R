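# independent oracles used across test files; these deliberately avoid the
# package's own solvers

# count roots of the rescaled dynamics by sign changes on a dense grid
dense_grid_root_count <- function(s, r, internal, n = 1e5) {
  ub <- r * (s + 1)
  x <- c(0, exp(seq(log(ub * 1e-9), log(ub), length.out = n)))
  cf <- 2 * x / (1 + sqrt(1 + 8 * x / internal$alpha))
  f <- cf^2 / (1 + (1 + 1 / internal$p) * cf^2 +
                 (internal$omega / internal$p) * cf^4)
  y <- s + f - x / r
  sum(diff(sign(y)) != 0) + as.integer(s == 0)
}

# plain bisection on a monotone function
bisect <- function(fun, lo, hi, tol = 1e-10, maxit = 200) {
  flo <- fun(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- fun(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

num_deriv <- function(fun, x, h = 1e-6) {
  (fun(x + h) - fun(x - h)) / (2 * h)
}

log_mid <- function(interval) exp(mean(log(interval)))
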