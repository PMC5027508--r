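# shared fixtures built in code

# toy anchors with short flanks satisfying the non-G boundary invariant;
# contexts long enough for min-length extension of tiny variants
toy_anchors <- function() {
  anchor_pair(upstream_flank = "ACTACT",        # rCRS-ascending convention
              downstream_flank = "TCATCA",
              strand_of_definition = "reference",
              upstream_context = "ATTGCCATTGCCATTGCC",
              downstream_context = "GGATCCGGATCCGGATCC")
}

# a record embedding one variant between the anchors of `anchors`
plant_record <- function(variant, anchors, id = variant,
                         on_reference = FALSE) {
  v <- if (is.character(variant)) parse_nomenclature(variant) else variant
  grich <- paste0(anchors$context5, anchors$flank5, tract_sequence(v),
                  anchors$flank3, anchors$context3)
  seq_record(id, if (on_reference) reverse_complement(grich) else grich)
}

# random interrupted frequency matrix on a small grid
random_matrix <- function(m_range = 1:6, n_range = 1:6, seed = 1,
                          interrupts = "A") {
  set.seed(seed)
  counts <- integer(0)
  for (x in interrupts) for (m in m_range) for (n in n_range)
    counts[paste0("G", m, x, "G", n)] <- rbinom(1, 50, 0.3)
  frequency_matrix(counts, m_range = m_range, n_range = n_range)
}
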