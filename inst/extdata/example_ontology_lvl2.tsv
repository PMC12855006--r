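term_id	super_term_id
t01	T01
t02	T01
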