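term	gene_symbol
actin_filament	Vil1
actin_filament	Baiap2l1
actin_filament	Ush1c
actin_filament	Actb
actin_filament	Myo1a
actin_filament	Ezr
actin_filament	Pls1
actin_filament	Espn
actin_filament	Myh9
actin_filament	Flnb
membrane	Atp1b1
membrane	Cdh1
membrane	Slc5a1
membrane	Anpep
membrane	Alpi
membrane	Ezr
cytoplasm	Gapdh
cytoplasm	Aldob
cytoplasm	Eno1
cytoplasm	Hspa8
cytoplasm	Sis
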