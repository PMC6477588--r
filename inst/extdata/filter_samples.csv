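arm,filter_id,total_mg_per_L,drug_ug_per_L
IHNP-LD,FS-1-L,0.247,80.05
IHNP-LD,FS-2-L,0.242,81.79
IHNP-LD,FS-3-L,0.252,87.09
IHNP-LD,FS-4-L,0.296,104.38
IHNP-LD,FS-5-L,0.247,78.47
IHNP-LD,FS-6-L,0.249,82.5
IHNP-LD,FS-7-L,0.244,85.19
IHNP-HD,FS-1-H,0.383,212.53
IHNP-HD,FS-2-H,0.412,239.28
IHNP-HD,FS-3-H,0.494,291.44
IHNP-HD,FS-4-H,0.516,296.56
IHNP-HD,FS-5-H,0.456,254.67
IHNP-HD,FS-6-H,0.501,289.5
IHNP-HD,FS-7-H,0.431,251.88
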