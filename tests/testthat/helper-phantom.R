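# Shared fixtures, built in code and cached per test file.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# coarse grid (2x-binned lateral pitch) used to keep phantom tests fast
coarse_voxel <- function() voxel_spec(0.434, 0.434, 0.5)

small_phantom <- function() cached("small_phantom", function() {
  generate_monolayer(2, 2, polarity_state("polarized"),
                     voxel = coarse_voxel(), seed = 11,
                     make_intensity = FALSE)
})

# rasterized ball on an isotropic unit grid
unit_ball <- function(r, n = 2 * r + 9) {
  xs <- seq_len(n) - 0.5 - n / 2
  array(outer(outer(xs^2, xs^2, `+`), xs^2, `+`) <= r^2, c(n, n, n))
}

# two-plane stack whose two strips overlap with IoU exactly k/100
strip_stack <- function(k, len = 100) {
  n <- len + k
  shift <- len - k
  width <- n + shift + 4L
  p1 <- matrix(0L, 3, width); p2 <- matrix(0L, 3, width)
  p1[2, 2 + seq_len(n)] <- 1L
  p2[2, 2 + shift + seq_len(n)] <- 1L
  list(p1, p2)
}

# stack with two coaxial cylinder fragments separated by `gap` empty planes
gap_stack <- function(gap, r = 6, frag = 3) {
  n <- 2 * r + 5
  xs <- seq_len(n) - 0.5 - n / 2
  disk <- outer(xs^2, xs^2, `+`) <= r^2
  empty <- matrix(0L, n, n)
  pl <- matrix(as.integer(disk), n, n)
  c(rep(list(pl), frag), rep(list(empty), gap), rep(list(pl), frag))
}
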