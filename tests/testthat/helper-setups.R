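# Shared fixtures: canonical genomes and crosses used across the suite.

acos_setup <- setup_acos_fire()
acos_lethal_setup <- setup_acos_fire(homozygous_lethal = TRUE)
unlinked_setup <- setup_agoc_acos(agoc_chromosome = "ChLG2")
linked_setup <- setup_agoc_acos(agoc_chromosome = "ChLG9")
xlinked_setup <- setup_agoc_acos(agoc_chromosome = "ChLGX")

# The canonical crosses exercised by Monte-Carlo agreement and round-trip
# property tests.
canonical_crosses <- function() {
  list(
    F3 = acos_cross(acos_setup, "F3"),
    F4 = acos_cross(acos_setup, "F4"),
    F6 = acos_cross(acos_setup, "F6"),
    hemi_sib = hemizygote_sibling_cross(acos_setup$genome, "ACOS"),
    F8_unlinked = agoc_acos_cross(unlinked_setup, "F8"),
    F9_unlinked = agoc_acos_cross(unlinked_setup, "F9"),
    F8_linked = agoc_acos_cross(linked_setup, "F8"),
    F9_linked = agoc_acos_cross(linked_setup, "F9"))
}

# Allele placement shorthand for lx_genotype().
al <- function(construct, state, homolog)
  list(construct = construct, state = state, homolog = homolog)

# Probability of a flavor class (summed over sexes/arrangements).
flavor_prob <- function(dist, flavor) sum(dist$prob[dist$flavor == flavor])
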