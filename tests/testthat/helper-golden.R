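# The seeded regression fixture used for the byte-for-byte golden tests:
# the default study conditions with a 12-gene pathway definition, which
# keeps the pairwise scan (and hence the committed reference outputs)
# small while leaving the 60-gene ORA universe intact.
golden_gene_sets <- function() {
  gs <- default_gene_sets()
  gs$FOCAL_ADHESION_SYN$genes <- sprintf("GENE%03d", 1:12)
  gs
}

golden_config <- function() sim_config(gene_sets = golden_gene_sets())

golden_seed <- 42
golden_perm_B <- 199
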