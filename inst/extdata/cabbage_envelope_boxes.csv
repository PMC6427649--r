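plant,measured_length_mm,measured_width_mm,measured_height_mm,theoretical_length_mm,theoretical_width_mm,theoretical_height_mm
a,263.68,240.60,151.48,264.16,234.12,153.98
b,307.86,306.12,230.46,318.46,305.63,186.58
c,316.68,245.24,155.22,319.66,252.43,155.78
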