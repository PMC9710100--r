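#' Six positional lncRNA categories
#'
#' Category names used throughout the package, in classification precedence
#' order (strongest physical overlap first).
#' @export
LNC_CATEGORIES <- c(
  "sense_overlapping", "intronic", "natural_antisense",
  "nonoverlapping_antisense", "bidirectional", "intergenic"
)
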