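## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    stop_invalid(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  if (integer && x != round(x))
    stop_invalid(sprintf("'%s' must be an integer", name))
  invisible(x)
}

check_matrix <- function(x, name = "image", finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(sprintf("'%s' must be a numeric matrix", name))
  if (finite && !all(is.finite(x)))
    stop_invalid(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

## symmetric round-half-away-from-zero; base round() goes half-to-even,
## which would break the exact 90-degree rotation of the filter-bank masks
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## 2D cross-correlation with symmetric (mirror) boundary padding.  Kernels in
## this package are point-symmetric, so correlation equals convolution.
conv2_reflect <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(hr:1, 1:nr, nr:(nr - hr + 1L))[seq_len(nr + 2L * hr)]
  ci <- c(hc:1, 1:nc, nc:(nc - hc + 1L))[seq_len(nc + 2L * hc)]
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kern[a, b]
      if (w != 0)
        out <- out + w * pad[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc)]
    }
  }
  out
}

## wrap angles to [0, pi) (axial) or [0, 2*pi)
wrap_axial <- function(theta) theta %% pi
wrap_circular <- function(theta) theta %% (2 * pi)

## von Mises sampler, Best & Fisher (1979) rejection scheme; kappa = 0 falls
## back to the uniform circle.  Uses the current RNG stream.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- wrap_circular(mu + sign(runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))))
      i <- i + 1L
    }
  }
  out
}

## digital disk structuring element: pixels within Euclidean distance
## r + 0.5 of the center (odd square of side 2r + 1)
disk_kernel <- function(r) {
  check_scalar(r, "r", lower = 0, integer = TRUE)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= (r + 0.5)^2
  storage.mode(k) <- "integer"
  k
}
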