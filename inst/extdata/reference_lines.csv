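# Packaged emission-line table for libsquant.
# Na and K rows carry the published resonance wavelengths used for
# quantification. Ca/Ba/Sr rows are SYNTHETIC fixture entries (plausible
# wavelengths, nominal relative strengths) intended for simulator demos
# and identification examples only; relative strengths throughout are
# nominal instrument-relative values, not NIST transition probabilities.
element,species,wavelength_nm,rel_strength
K,I,766.39,1.00
K,I,769.98,0.50
Na,I,589.18,1.00
Na,I,819.22,0.25
Ca,II,393.37,1.00
Ca,II,396.85,0.50
Ca,I,422.67,0.60
Ba,II,455.40,1.00
Ba,II,493.41,0.60
Ba,I,553.55,0.40
Sr,II,407.77,1.00
Sr,II,421.55,0.60
Sr,I,460.73,0.30
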