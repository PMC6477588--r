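arm,matrix,time_hr,mean,sd,n_quantified,n_total
IVnP,plasma,0.5,206,44.1,3,3
IVnP,plasma,6,62.2,9.2,3,3
IVnP,plasma,12,20,0.9,3,3
IVnP,plasma,24,15.3,4.4,3,3
IVnP,plasma,48,2.98,1.5,3,3
IVnP,plasma,72,1.05,,1,3
IVnP,plasma,120,,,0,3
IVnP,plasma,168,,,0,3
IVnP,plasma,240,,,0,3
IVnP,plasma,336,,,0,3
IVnP,lung,0.5,5800,430.1,3,3
IVnP,lung,6,2730,106.4,3,3
IVnP,lung,12,1170,113.7,3,3
IVnP,lung,24,647,188.6,3,3
IVnP,lung,48,244,48.1,3,3
IVnP,lung,72,145,54,3,3
IVnP,lung,120,,,0,3
IVnP,lung,168,,,0,3
IVnP,lung,240,,,0,3
IVnP,lung,336,,,0,3
IHNP-LD,plasma,0.5,11.6,3.5,3,3
IHNP-LD,plasma,6,2.87,0.4,3,3
IHNP-LD,plasma,12,3.35,1.4,3,3
IHNP-LD,plasma,24,1.26,0.1,2,3
IHNP-LD,plasma,48,,,0,3
IHNP-LD,plasma,72,,,0,3
IHNP-LD,plasma,120,,,0,3
IHNP-LD,plasma,168,,,0,3
IHNP-LD,plasma,240,,,0,3
IHNP-LD,plasma,336,,,0,3
IHNP-LD,lung,0.5,21000,3503.1,3,3
IHNP-LD,lung,6,4990,1219.1,3,3
IHNP-LD,lung,12,5368,764.1,3,3
IHNP-LD,lung,24,3008,1170,3,3
IHNP-LD,lung,48,1247,288.9,3,3
IHNP-LD,lung,72,950,355.2,3,3
IHNP-LD,lung,120,1045,327.1,3,3
IHNP-LD,lung,168,377,236.1,3,3
IHNP-LD,lung,240,109,38.4,3,3
IHNP-LD,lung,336,55.5,,1,3
IHNP-HD,plasma,0.5,15.9,4.3,3,3
IHNP-HD,plasma,6,5.69,1,3,3
IHNP-HD,plasma,12,4.95,1.6,3,3
IHNP-HD,plasma,24,1.96,0.8,3,3
IHNP-HD,plasma,48,1.21,,1,3
IHNP-HD,plasma,72,1.06,,1,3
IHNP-HD,plasma,120,,,0,3
IHNP-HD,plasma,168,,,0,3
IHNP-HD,plasma,240,,,0,3
IHNP-HD,plasma,336,,,0,3
IHNP-HD,lung,0.5,41600,1557.8,3,3
IHNP-HD,lung,6,20800,4499.6,3,3
IHNP-HD,lung,12,14700,1661.8,3,3
IHNP-HD,lung,24,11433,838,3,3
IHNP-HD,lung,48,6700,535.4,3,3
IHNP-HD,lung,72,3953,863.5,3,3
IHNP-HD,lung,120,1923,846.1,3,3
IHNP-HD,lung,168,2143,889.4,3,3
IHNP-HD,lung,240,430,122.8,3,3
IHNP-HD,lung,336,272,67.5,3,3
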