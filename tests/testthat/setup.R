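# A deliberately strict end-to-end block can accumulate several expectation
# failures; never let that truncate the rest of the suite.
options(testthat.progress.max_fails = 1000L)
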