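# Shared fixtures, built once per run and cached.

.fixtures <- new.env(parent = emptyenv())

small_anatomy <- function(shape = c(32, 32, 24), seed = 1) {
  key <- paste(c(shape, seed), collapse = "_")
  if (is.null(.fixtures[[key]])) {
    lab <- generate_label_volume(shape, seed = seed)
    props <- generate_property_volumes(lab, seed = seed)
    .fixtures[[key]] <- list(labels = lab, props = props)
  }
  .fixtures[[key]]
}

# Hand-built anatomy: labels from an integer array, property volumes from
# explicit arrays, bypassing the procedural generator.
toy_anatomy <- function(lab_arr, water, fat, r2) {
  labels <- qsmphantom:::new_tissue_labels(lab_arr)
  # toy property maps are often deliberately constant; the degenerate
  # normalization warning is expected there
  props <- suppressWarnings(
    qsmphantom:::new_property_volumes(water, fat, r2, labels))
  list(labels = labels, props = props)
}

# Minimal tissue-parameter rows for toy classes.
toy_params <- function(class_id, chi_mean = 0, a = 0, b = 0, cc = 0,
                       r2_mean = NA, a_r2 = NA, modify_r2 = 0,
                       smooth_excluded = 0) {
  data.frame(class_id = class_id, class = paste0("c", class_id),
             chi_mean_ppm = chi_mean, a_ppm = a, b_ppm = b, c_ppm = cc,
             r2_mean_hz = r2_mean, a_r2_hz = a_r2, modify_r2 = modify_r2,
             smooth_excluded = smooth_excluded, background_source = 0,
             stats_excluded = 0)
}

# Centered sphere mask and coordinates on an n^3 grid.
sphere_setup <- function(n, radius) {
  g <- seq_len(n) - (n + 1) / 2
  X <- array(g, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  chi <- array(0, c(n, n, n))
  chi[r <= radius] <- 1
  list(chi = chi, r = r, Z = Z)
}

GAMMA <- 42.5775e6
LOBE_ID <- 24L

new_field_map_for_test <- function(field, b0 = 3, gamma = GAMMA) {
  qsmphantom:::new_field_map(field, b0 = b0, gamma = gamma)
}

# Zero-local-mean oscillatory 3D pattern (for sign-sensitive similarity
# checks).
axis_pattern <- function(n, amplitude = 0.3) {
  g <- sin(2 * pi * seq_len(n) / 4)
  a <- qsmphantom:::axis_grid(g, g, g)
  amplitude * a$x * a$y * a$z
}
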