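# Synthetic stand-in list of total-hysterectomy procedure codes (ACHI-style).
# The codes screened in a real study are jurisdiction- and coding-edition-
# specific and must be supplied by the analyst; this file only demonstrates
# the expected format (one code per line, '#' comments ignored).
3565300
3565301
3565800
3566100
3565304
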