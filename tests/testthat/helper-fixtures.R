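# Fixtures built in code. The phantom bundle used by several files is
# cached per session (geometry is deterministic; noise is seeded).

.fixture_env <- new.env(parent = emptyenv())

phantom_fixture <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- make_phantom(phantom_spec(seed = 11L))
  .fixture_env$bundle
}

# sphere indicator volume on an identity-direction grid
sphere_indicator <- function(center, radius, spacing = c(1, 1, 1),
                             dims = c(32, 32, 32),
                             origin = -(dims - 1) * spacing / 2) {
  g <- grid3d(origin = origin, spacing = spacing, dims = dims)
  ax <- list(x = origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
             y = origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
             z = origin[3] + (seq_len(dims[3]) - 1) * spacing[3])
  d2 <- outer(outer((ax$x - center[1])^2, (ax$y - center[2])^2, "+"),
              (ax$z - center[3])^2, "+")
  list(grid = g, arr = array(as.numeric(d2 <= radius^2), dim = dims))
}

# axis-aligned box mask in voxel index ranges (1-based, inclusive)
box_mask <- function(dims, i, j, k) {
  m <- array(0, dims)
  m[i[1]:i[2], j[1]:j[2], k[1]:k[2]] <- 1
  m
}

# random non-empty blob mask: union of 1-3 random boxes and spheres
random_mask <- function(dims, spacing = c(1, 1, 1)) {
  m <- array(0, dims)
  for (s in seq_len(sample(1:2, 1))) {
    c0 <- sapply(dims, function(d) runif(1, 2, d - 1))
    r <- runif(1, 1.5, min(dims) / 3)
    idx <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
    d2 <- rowSums(sweep(idx, 2, c0)^2)
    m[idx[d2 <= r^2, , drop = FALSE]] <- 1
  }
  if (sum(m) == 0) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                     ceiling(dims[3] / 2)] <- 1
  m
}

# grayscale ramp transfer function used in renderer tests
gray_ramp_tf <- function(vmin, vmax, max_alpha = 0.6) {
  transfer_function(values = c(vmin, vmax),
                    colors = rbind(c(0, 0, 0, 0), c(1, 1, 1, max_alpha)))
}
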