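# Small image configurations used across tests: same pixel size and optics
# as the full-size default, fewer pixels/slices/nuclei so tests stay fast.
small_image_cfg <- function(...) {
  args <- utils::modifyList(
    list(image_width_px = 512L, image_height_px = 512L, n_slices = 3L,
         n_fields = 2L, nuclei_per_field = 5L, seed = 11L),
    list(...)
  )
  do.call(image_gen_config, args)
}

noise_free_cfg <- function(...) {
  small_image_cfg(noise_sd = 0, gain = 0, ...)
}

# Brute-force Kapur threshold: literal double loop over every candidate
# split, recomputing both class entropies from scratch.
brute_force_max_entropy <- function(counts, levels = seq_along(counts) - 1) {
  p <- counts / sum(counts)
  n <- length(p)
  best_h <- -Inf
  best_t <- NA
  for (s in 1:(n - 1)) {
    p1 <- p[1:s]
    p2 <- p[(s + 1):n]
    w1 <- sum(p1)
    w2 <- sum(p2)
    if (w1 <= 0 || w2 <= 0) next
    q1 <- p1[p1 > 0] / w1
    q2 <- p2[p2 > 0] / w2
    h <- -sum(q1 * log(q1)) - sum(q2 * log(q2))
    if (h > best_h) {
      best_h <- h
      best_t <- levels[s]
    }
  }
  best_t
}

# A lane profile sampled on a fine regular grid.
make_profile <- function(f, from = 0, to = 100, n = 2001) {
  x <- seq(from, to, length.out = n)
  tibble::tibble(position = x, intensity = f(x))
}
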