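pt_name	pt_code
Hyperprolactinaemia	10020870
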