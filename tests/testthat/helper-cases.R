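# shared fixtures: the bundled three-scale case study and its correlation
whey <- whey_scaleup_cases()
whey_corr <- attr(whey, "correlation")

# relative error against a reference value
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# agreement with a printed table cell: within `rel` relative error or within
# half a unit in the last printed digit (printed rounding), whichever is wider
agrees_with_printed <- function(x, printed, rel = 0.01, decimals = 2) {
  abs(x - printed) <= max(rel * abs(printed), 0.5 * 10^(-decimals))
}
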