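# The full (omega, k, drive) sweep is deterministic and takes ~10 s; compute
# it once per test run and share it across test blocks.
.sweep_cache <- new.env(parent = emptyenv())

full_sweep <- function() {
  if (is.null(.sweep_cache$sw)) .sweep_cache$sw <- sweep_oscillator()
  .sweep_cache$sw
}
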