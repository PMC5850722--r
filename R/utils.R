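# Internal numerical helpers shared across modules.

# log(sum(exp(x))) with max subtraction; tolerates -Inf entries.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Locale-independent sort order for character keys.
radix_order <- function(x) order(x, method = "radix")

# Key string for a species set given as a logical membership vector.
block_key <- function(block, species) paste(species[block], collapse = ";")
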