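# Shared fixtures (built lazily, cached for the whole run) and independent
# brute-force oracle implementations used to cross-check the package's
# vectorized/compiled code paths.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# small dataset: 6 cases, 64^3 voxels, 1 bone + 2 bilateral muscles
tiny_manifest <- function() {
  fixture("tiny_manifest", function() {
    specs <- lapply(1:6, function(s)
      phantom_spec(grid_shape = c(64, 64, 64), spacing = c(3, 3, 3),
                   n_bones = 1, n_muscles = 2, asymmetry_factor = 0.85,
                   seed = s))
    build_dataset(specs, splits = c(train = 0.5, val = 0.25, test = 0.25),
                  seed = 11)
  })
}

tiny_phantom <- function() {
  fixture("tiny_phantom", function()
    generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                  spacing = c(4, 4, 4), n_bones = 3,
                                  n_muscles = 4, seed = 2)))
}

# two axis-aligned boxes in air, used for integrator cross-checks
two_box_phantom <- function() {
  fixture("two_box", function() {
    ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                        spacing = c(2, 2, 2), n_bones = 1,
                                        n_muscles = 1, seed = 1))
    ph$hu[] <- -1000
    ph$label[] <- 0L
    ph$hu[6:15, 8:20, 6:26] <- 60
    ph$label[6:15, 8:20, 6:26] <- 1L
    ph$hu[20:28, 10:22, 10:20] <- 400
    ph$label[20:28, 10:22, 10:20] <- 2L
    ph$n_channels <- 3L
    ph
  })
}

# --- brute-force oracles -----------------------------------------------------

brute_filter3 <- function(x, kern) {
  h <- nrow(x); w <- ncol(x)
  refl <- function(q, n) { if (q < 1) q <- 2 - q; if (q > n) q <- 2 * n - q; q }
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      acc <- acc + kern[di + 2, dj + 2] *
        x[refl(i + di, h), refl(j + dj, w)]
    }
    out[i, j] <- acc
  }
  out
}

brute_ncc <- function(a, b, eps = 1e-8) {
  am <- 0; bm <- 0; n <- length(a)
  for (v in a) am <- am + v / n
  for (v in b) bm <- bm + v / n
  s <- 0; va <- 0; vb <- 0
  for (i in seq_len(n)) {
    s <- s + (a[i] - am) * (b[i] - bm)
    va <- va + (a[i] - am)^2
    vb <- vb + (b[i] - bm)^2
  }
  s / sqrt(va * vb + eps)
}

brute_gc <- function(a, b) {
  su <- outer(c(1, 2, 1), c(-1, 0, 1))
  sv <- outer(c(-1, 0, 1), c(1, 2, 1))
  (brute_ncc(brute_filter3(a, su), brute_filter3(b, su)) +
     brute_ncc(brute_filter3(a, sv), brute_filter3(b, sv))) / 2
}

brute_psnr <- function(pred, truth, peak) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - truth[i])^2
  10 * log10(peak^2 / (s / length(pred)))
}

brute_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  2 * inter / (na + nb)
}
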