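# Shared fixtures, built once per test run. Small sizes keep the suite fast;
# the acceptance tests rebuild their own inputs at full scale.

fix <- local({
  dirs60 <- generate_directions(60, seed = 1234)
  dirs30 <- generate_directions(30, seed = 1234)
  subs <- preset_substrates()
  # the optimised preclinical pair (b = 8, G_max = 600) printed protocols
  w_s1 <- sde_waveform(6.9, 8.9, b = 8)
  w_s2o <- sde_waveform(14.1, 31, b = 8)
  list(dirs60 = dirs60, dirs30 = dirs30, subs = subs,
       w_s1 = w_s1, w_s2o = w_s2o)
})
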