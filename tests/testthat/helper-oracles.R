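## Independent oracles and small fixture builders shared across tests.

## brute-force binary opening with the same digital disk (pixels within
## Euclidean distance r + 0.5), written as explicit shift-min / shift-max
## passes, independent of the morphology backend used by the package
brute_disk_offsets <- function(r) {
  d <- seq(-r, r)
  idx <- which(outer(d^2, d^2, "+") <= (r + 0.5)^2, arr.ind = TRUE)
  idx - (r + 1L)
}

brute_shift <- function(m, dr, dc, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) + dr
  cs <- seq_len(ncol(m)) + dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

brute_open_area <- function(pores, r) {
  if (r == 0) return(sum(pores))
  off <- brute_disk_offsets(r)
  pad <- r
  P <- matrix(0, nrow(pores) + 2 * pad, ncol(pores) + 2 * pad)
  P[pad + seq_len(nrow(pores)), pad + seq_len(ncol(pores))] <- pores
  er <- matrix(1, nrow(P), ncol(P))
  for (i in seq_len(nrow(off)))
    er <- pmin(er, brute_shift(P, off[i, 1], off[i, 2], 0))
  di <- matrix(0, nrow(P), ncol(P))
  for (i in seq_len(nrow(off)))
    di <- pmax(di, brute_shift(er, -off[i, 1], -off[i, 2], 0))
  sum(di[pad + seq_len(nrow(pores)), pad + seq_len(ncol(pores))])
}

brute_pore_retained <- function(mask, max_r) {
  pores <- 1 - mask
  vapply(0:max_r, function(r) brute_open_area(pores, r), numeric(1))
}

## direct O(n^2 k^2) cross-correlation with mirror padding, independent of
## the package's shift-based implementation
brute_conv_reflect <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(hr:1, 1:nr, nr:(nr - hr + 1L))[seq_len(nr + 2L * hr)]
  ci <- c(hc:1, 1:nc, nc:(nc - hc + 1L))[seq_len(nc + 2L * hc)]
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      out[i, j] <- sum(kern * pad[i:(i + kr - 1L), j:(j + kc - 1L)])
  out
}

## 90-degree rotation of a matrix
rot90 <- function(m) t(m)[, seq(nrow(m), 1), drop = FALSE]

## small fiber image for repeated use
make_fiber_field <- function(kappa, seed, size = 256, n_fibers = 150,
                             length = 120, width = 3, ...) {
  generate_fiber_image(fiber_field_params(
    image_size_px = size, n_fibers = n_fibers, mean_length_px = length,
    width_px = width, orientation_kappa = kappa, seed = seed, ...))
}

## mean resultant length of axial angles (doubled-angle convention)
axial_mrl <- function(theta) Mod(mean(exp(2i * theta)))
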