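.onLoad <- function(libname, pkgname) {
  # single-threaded BLAS: bit-reproducible training/inference independent of
  # the host's core count (GEMM reduction order fixed)
  invisible(.cpp_set_blas_threads(1L))
}
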