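consequence	mutation_class	non_silent
missense_variant	missense	TRUE
stop_gained	nonsense	TRUE
stop_lost	missense	TRUE
start_lost	missense	TRUE
frameshift_variant	frameshift	TRUE
inframe_insertion	in-frame indel	TRUE
inframe_deletion	in-frame indel	TRUE
disruptive_inframe_insertion	in-frame indel	TRUE
disruptive_inframe_deletion	in-frame indel	TRUE
splice_acceptor_variant	splice	TRUE
splice_donor_variant	splice	TRUE
splice_region_variant	splice	TRUE
synonymous_variant	silent	FALSE
stop_retained_variant	silent	FALSE
start_retained_variant	silent	FALSE
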