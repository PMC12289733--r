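.onLoad <- function(libname, pkgname) {
  register_model(.mle_contract())
  register_model(.bci_contract())
  register_model(.net_av_contract())
  register_model(.net_stci_contract())
  invisible()
}
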