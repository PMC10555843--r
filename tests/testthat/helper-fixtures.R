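# Small shared helpers: tiny network configs and movies built in code.

tiny_config <- function(...) {
  support_config(n_before = 2L, n_after = 2L, bs_depth = 2L,
                 bs_channels = 4L, unet_depth = 2L,
                 unet_base_channels = 4L, ...)
}

random_window <- function(net_cfg, h = 16L, w = 16L, n = 1L, seed = 1L) {
  set.seed(seed)
  tw <- net_cfg$n_before + 1L + net_cfg$n_after
  array(rnorm(h * w * tw * n), c(h, w, tw, n))
}

small_movie <- function(t_n = 40L, h = 12L, w = 12L, seed = 5L) {
  set.seed(seed)
  base <- outer(seq_len(h), seq_len(w), function(i, j) 10 + i + 0.5 * j)
  out <- array(0, c(t_n, h, w))
  for (t in seq_len(t_n)) out[t, , ] <- base + rnorm(h * w, sd = 0.5)
  out
}
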