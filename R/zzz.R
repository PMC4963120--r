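#' @importFrom rlang .data
NULL

.onLoad <- function(libname, pkgname) {
  # Built-in detectors. "greedy_density" is the package's own baseline, not
  # a reimplementation of any published detection method; "whole_subnetwork"
  # returns each subnetwork's node set and is mainly useful in tests.
  register_detector("greedy_density", function(sub, params) {
    do.call(greedy_density_detect, c(list(sub), params))
  })
  register_detector("whole_subnetwork", function(sub, params) {
    if (length(sub$proteins)) list(sort(sub$proteins)) else list()
  })
  invisible()
}
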