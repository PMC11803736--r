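# Shared fixtures: the reference molecule at the reported degree of
# polymerisation, and its shape templates.
ref_derived <- function() {
  derive_size_parameters(parg_primitives(), n_monomers = 240)
}
ref_shape <- function(diameter = "condensed") {
  molecule_shape(ref_derived(), diameter = diameter)
}
disk_shape <- function(d = 1) spherocylinder_shape(d, d)
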