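# The reproduction tests fail (by design) when their deposited inputs are
# absent; keep the progress reporter from terminating the run early so the
# synthetic suite always executes in full.
options(testthat.progress.max_fails = 500L)
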