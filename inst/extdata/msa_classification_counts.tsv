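# Published processing-tree bookkeeping counts for the MSA ex vivo
# alpha-synuclein cryo-EM dataset whose polymorph analysis this package
# models. Plain inputs for share/ratio arithmetic; not computed here.
quantity	count
micrographs_total	4392
micrographs_with_I2	437
segments_extracted	257982
segments_after_2d	255032
class3d_I2_segments	12802
class3d_II2_clean_segments	57809
class3d_II2_realigned_segments	110071
class3d_II2_refined_segments	31115
abinitio_II2_segments	206869
abinitio_I2_segments	15369
filaments_in_selected_micrographs	556
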