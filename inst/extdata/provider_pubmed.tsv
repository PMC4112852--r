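raw_query	record_ids
tyrosine aminotransferase and malaria	ref23
ppar gamma and type 2 diabetes	ref25
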