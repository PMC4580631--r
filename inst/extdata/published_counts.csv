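measure,group,value
n,statin,27594
n,fibrate,4058
events,statin,1026
events,fibrate,167
combo_first_year,fibrate,18
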