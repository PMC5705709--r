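# Molar extinction coefficients of oxy- and deoxy-hemoglobin (cm^-1 / M),
# 500-600 nm in 10 nm steps, adapted from the standard compiled tabulation
# (Prahl compilation). Values are approximate and used in relative units
# only; the forward phantom model and the unmixing inverse share this asset.
# version: 1
wavelength_nm,eps_hbo2,eps_hb
500,20932.8,20862.0
510,20035.2,25773.6
520,24202.4,31589.6
530,39956.8,39036.4
540,53236.0,46592.0
550,43016.0,52276.0
560,32613.2,53292.0
570,44496.0,50104.0
580,48000.0,37020.0
590,9000.0,26600.4
600,3200.0,14677.2
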