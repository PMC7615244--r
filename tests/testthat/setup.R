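# Report every expectation: some documented engine-limitation checks fail
# by design, and the default failure budget would otherwise stop the run
# before later files execute.
options(testthat.progress.max_fails = 1000)
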