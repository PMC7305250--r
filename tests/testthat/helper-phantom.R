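# Shared fixtures: small phantoms built in code at test time.

# A compact noise-free phantom: T11, T12, L1, L2 in a 110 x 48 x 48 grid
# at (1, 2, 2) mm spacing.
small_phantom <- function(noise_sd = 0, seed = 1, ...) {
  generate_phantom(phantom_spec(n_thoracic = 2, n_lumbar = 2,
                                noise_sd = noise_sd, seed = seed,
                                volume_shape = c(110, 48, 48), ...))
}

# Filled disk as a logical matrix (voxel-center rasterization).
disk_region <- function(radius, nrow = 2 * radius + 21, ncol = 2 * radius + 21,
                        center = NULL) {
  if (is.null(center)) center <- c((nrow + 1) / 2, (ncol + 1) / 2)
  r2 <- outer((seq_len(nrow) - center[1])^2, (seq_len(ncol) - center[2])^2, `+`)
  r2 <= radius^2
}

# Axis-aligned box instance in a class mask, for labeling tests.
add_box <- function(arr, z, y, x, value) {
  arr[z, y, x] <- value
  arr
}
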