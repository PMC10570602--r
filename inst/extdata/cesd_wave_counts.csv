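wave,n_total,n_depressed
2013,3887,1134
2015,3887,949
2018,3887,1255
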