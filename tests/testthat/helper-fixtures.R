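# Shared fixtures, built lazily and cached for the session.

# full-length white-noise reference (2,500-sample epochs); the shape
# intervals use a reduced Monte Carlo (2,000 epochs) -- endpoint accuracy
# at the 1e4-epoch scale is exercised by the acceptance suite
ref2500 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_noise_reference(2500, n_epochs = 2000, seed = 11,
                                      n_cloud_epochs = 100)
    cache
  }
})

# small reference for error-path and serialization tests
ref512 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_noise_reference(512, n_epochs = 300, seed = 5,
                                      n_cloud_epochs = 30)
    cache
  }
})

tone <- function(freq, n = 2500, rate = 500, amp = 1, phase = 0) {
  t <- (seq_len(n) - 1) / rate
  amp * sin(2 * pi * freq * t + phase)
}

# tiny SPP architecture for fast classifier plumbing tests
tiny_spp_config <- function(...) {
  args <- utils::modifyList(
    list(conv_channels = c(2L, 4L),
         conv_kernels = list(c(4L, 3L), c(2L, 2L)),
         conv_strides = list(c(2L, 1L), c(1L, 1L)),
         conv_pad_w = c(0L, 1L),
         levels = c(2L, 1L), fc_sizes = c(8L, 2L),
         epochs = 3L, lr = 0.01, batch = 8L, seed = 1L),
    list(...))
  do.call(spp_config, args)
}
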