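label	or	ci_lower	ci_upper
scan 1	1.09	1.01	1.16
scan 2	1.23	1.09	1.41
scan 3	1.20	1.07	1.33
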