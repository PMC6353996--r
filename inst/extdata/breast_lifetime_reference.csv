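cell_line,status,tau1_ns,tau1_se_ns,tau2_ns,tau2_se_ns
MDA-MB-231,cancer,0.266,0.005,0.751,0.013
MDA-MB-157,cancer,0.273,0.005,0.748,0.013
MCF-12A,normal,0.304,0.005,0.894,0.015
MCF-10A,normal,0.300,0.003,0.946,0.009
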