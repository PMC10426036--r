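# Counter-based seed derivation: stages and reference-table rows get their own
# reproducible stream independent of execution order. Result stays below 2^31.
derive_seed <- function(seed, i) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 7919
  as.integer(x %% 2147483647) + 1L
}

# One character per component token; adist() then computes token-level
# Levenshtein distance. Symbol indices are offset by 1 to avoid NUL.
encode_component_strings <- function(comp, n_comp) {
  vapply(seq_len(nrow(comp)),
         function(i) intToUtf8(comp[i, seq_len(n_comp[i])] + 1L),
         character(1))
}

#' Total variation distance between two frequency distributions
#'
#' Vectors are padded with zeros to a common length; each must sum to 1.
#'
#' @param p,q non-negative numeric vectors summing to 1.
#' @return distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  len <- max(length(p), length(q))
  p <- c(p, numeric(len - length(p)))
  q <- c(q, numeric(len - length(q)))
  0.5 * sum(abs(p - q))
}
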