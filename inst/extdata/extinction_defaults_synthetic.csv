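# Synthetic literature-shaped extinction coefficients of breast-tissue
# constituents at the seven measurement wavelengths.
# Units: Hb, HbO2 in cm^-1 / uM; water, lipid, collagen in cm^-1 / (mg/cm^3).
# These defaults reproduce the qualitative spectral features of the
# constituents (hemoglobin dominance below 800 nm, lipid peak near 930 nm,
# water peak near 975 nm, collagen sensitivity at 685 and 1060 nm); they are
# NOT measured values and all quantitative analyses in this package are
# round-trip consistent by construction, never dependent on these numbers.
wavelength_nm,Hb,HbO2,water,lipid,collagen
635,0.0101,0.00138,0.0000032,0.0000022,0.000030
685,0.00587,0.00064,0.0000049,0.0000022,0.000026
785,0.00180,0.00170,0.0000235,0.0000055,0.000016
905,0.00180,0.00280,0.0000680,0.0000490,0.000022
930,0.00170,0.00290,0.0001200,0.0001260,0.000028
975,0.00150,0.00265,0.0004500,0.0000600,0.000030
1060,0.00100,0.00230,0.0001300,0.0000550,0.000065
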