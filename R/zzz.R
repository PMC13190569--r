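.onLoad <- function(libname, pkgname) {
  # built-in deterministic encoders under their config names
  register_encoder("point_descriptor", encode_point_cloud)
  register_encoder("rgb_descriptor", encode_image)
  register_encoder("env_convlstm", encode_environment)
  invisible()
}
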