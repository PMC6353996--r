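cell_line,status,compartment,mb_mg_per_ml,mean_fpol_x100,se_fpol_x100,n_cells
MDA-MB-231,cancer,whole_cell,0.05,24.91,0.15,103
MDA-MB-157,cancer,whole_cell,0.05,25.16,0.14,105
MCF-12A,normal,whole_cell,0.05,22.29,0.14,103
MCF-10A,normal,whole_cell,0.05,20.88,0.12,104
MDA-MB-231,cancer,excl_nucleus,0.05,23.89,0.13,103
MDA-MB-157,cancer,excl_nucleus,0.05,24.24,0.13,105
MCF-12A,normal,excl_nucleus,0.05,21.06,0.13,103
MCF-10A,normal,excl_nucleus,0.05,20.21,0.11,104
MDA-MB-231,cancer,nucleus,0.05,25.37,0.11,103
MDA-MB-157,cancer,nucleus,0.05,25.43,0.11,105
MCF-12A,normal,nucleus,0.05,23.52,0.11,103
MCF-10A,normal,nucleus,0.05,22.33,0.10,104
MDA-MB-231,cancer,whole_cell,0.01,25.09,0.15,117
MDA-MB-157,cancer,whole_cell,0.01,25.02,0.13,100
MCF-12A,normal,whole_cell,0.01,22.05,0.16,113
MCF-10A,normal,whole_cell,0.01,21.68,0.17,111
MDA-MB-231,cancer,excl_nucleus,0.01,24.77,0.12,117
MDA-MB-157,cancer,excl_nucleus,0.01,24.90,0.10,100
MCF-12A,normal,excl_nucleus,0.01,21.34,0.12,113
MCF-10A,normal,excl_nucleus,0.01,21.01,0.13,111
MDA-MB-231,cancer,nucleus,0.01,25.54,0.10,117
MDA-MB-157,cancer,nucleus,0.01,25.28,0.09,100
MCF-12A,normal,nucleus,0.01,24.35,0.11,113
MCF-10A,normal,nucleus,0.01,23.48,0.12,111
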