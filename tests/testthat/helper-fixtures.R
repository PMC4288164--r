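# Shared fixtures: everything is generated in code at test time.

# unit-area Gaussian IRF on the default grid (40 ps FWHM, 40 ps/channel)
defaultIrf <- function(grid = ChannelGrid()) {
  makeIrf(SimulationSpec(MultiExpParams(1, 1), grid = grid, seed = 1L),
          unitArea = TRUE)
}

# delta-function IRF (zero-width limit) on a given grid
deltaIrf <- function(grid = ChannelGrid()) {
  w <- numeric(nChannels(grid))
  w[t0Channel(grid)] <- 1
  DecayTrace(w, grid, kind = "irf")
}

simpleSpec <- function(alphas = 1, taus = 11.3, seed = 1L, ...) {
  SimulationSpec(MultiExpParams(alphas, taus), seed = seed, ...)
}
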