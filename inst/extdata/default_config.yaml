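min_len: 75.6
max_len: 123.2
de_lo: 0.1366071
de_hi: 0.2655172
gravy_lo: -0.7851724
gravy_hi: -0.3064286
glypro_lo: 0.0642857
glypro_hi: 0.0916667
ratio_min: 2.55
mass_lo: 8528.151816
mass_hi: 14680.624464
esi_mode: strict_natural
glypro_enabled: yes
extra_patterns: []
gc_bin_width: 5.0
gc_priority_range:
- 25.0
- 35.0
orf_min_len: 40
length_check: post_trim
circular: no
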