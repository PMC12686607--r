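Editable ligand region maps (atom label -> region) for contact annotation
of the four SIRT6 complexes. Atom labels follow the deposited ligand
naming; these maps cover the atoms highlighted in the published contact
panels and are meant to be extended by the user to all heavy atoms before
use with annotate_contact()/run_pipeline().
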