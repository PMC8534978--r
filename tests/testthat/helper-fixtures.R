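extdata <- function(name) {
  path <- system.file("extdata", name, package = "oxikin")
  stopifnot(nzchar(path))
  path
}

# regression lines (slope, intercept) for the oleic-acid system with
# carnosic acid / TBHQ, as tabulated in the antioxidant literature
reference_fits <- function() {
  utils::read.csv(extdata("reference_fits.csv"), stringsAsFactors = FALSE)
}

ref_line <- function(fits, sample, method) {
  fits[fits$sample == sample & fits$method == method, , drop = FALSE]
}
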