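# Demo pipeline configuration: seven 2-AP probe sites with ground-truth
# parameters typical of a folded RNA at 20C (two-component intensity
# decays, biexponential anisotropy with local ~0.3 ns and global ~8 ns
# rotation, site-specific quenching constants).
seed: 20
grid:
  n_channels: 1024
  dwell_ns: 0.04
  t0_channel: 26
irf_fwhm_ns: 0.04
peak_counts: 10000
g_factor: 1.15
n_components: 2
quencher_concentrations_mM: [0, 25, 50, 100, 150, 200]
sites:
  - site: 6
    intensity: {alphas: [0.6, 0.4], taus_ns: [0.3, 2.2]}
    anisotropy: {r0: 0.31, betas: [0.673, 0.327], phis_ns: [0.3, 8.0]}
    kq_1e9: 4.7
  - site: 10
    intensity: {alphas: [0.4, 0.6], taus_ns: [0.3, 2.9]}
    anisotropy: {r0: 0.31, betas: [0.590, 0.410], phis_ns: [0.3, 8.0]}
    kq_1e9: 7.0
  - site: 24
    intensity: {alphas: [0.5, 0.5], taus_ns: [0.3, 3.08]}
    anisotropy: {r0: 0.31, betas: [0.668, 0.332], phis_ns: [0.3, 8.0]}
    kq_1e9: 20.4
  - site: 27
    intensity: {alphas: [0.5, 0.5], taus_ns: [0.28, 2.4]}
    anisotropy: {r0: 0.31, betas: [0.839, 0.161], phis_ns: [0.3, 8.0]}
    kq_1e9: 20.3
  - site: 35
    intensity: {alphas: [0.4, 0.6], taus_ns: [0.4, 2.77]}
    anisotropy: {r0: 0.31, betas: [0.834, 0.166], phis_ns: [0.3, 8.0]}
    kq_1e9: 4.2
  - site: 38
    intensity: {alphas: [0.6, 0.4], taus_ns: [0.25, 1.9]}
    anisotropy: {r0: 0.31, betas: [0.799, 0.201], phis_ns: [0.3, 8.0]}
    kq_1e9: 8.9
  - site: 41
    intensity: {alphas: [0.5, 0.5], taus_ns: [0.24, 2.2]}
    anisotropy: {r0: 0.31, betas: [0.897, 0.103], phis_ns: [0.3, 8.0]}
    kq_1e9: 6.8
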