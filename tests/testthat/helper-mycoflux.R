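# Small study configurations used across tests; sizes chosen so the whole
# suite runs in seconds while keeping the 9-isolate x 3-replicate design.
tiny_cfg <- function(...) {
  sim_config(
    n_plant_transcripts = 600, n_fungal_transcripts = 300,
    n_planted_pos = 20, n_planted_neg = 20,
    ...
  )
}

# brute-force percentile selection used as an oracle for select_percentiles
brute_top_bottom <- function(r) {
  n <- length(r)
  m <- ceiling(0.01 * n)
  ord <- order(r)
  list(top = sort(ord[(n - m + 1):n]), bottom = sort(ord[1:m]), m = m)
}

# letter-sharing matrix of a compact letter display: TRUE where two groups
# share at least one letter
sharing_matrix <- function(letters_chr, groups) {
  sets <- strsplit(letters_chr, "")
  names(sets) <- groups
  outer(groups, groups, Vectorize(function(a, b) {
    length(intersect(sets[[a]], sets[[b]])) > 0
  }))
}
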