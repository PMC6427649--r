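image,manual_area_px,theoretical_area_px,intersection_area_px,sensitivity_percent
a,108000,97600,84800,86.91
b,70000,64800,57400,82.07
c,37900,37300,33600,88.75
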