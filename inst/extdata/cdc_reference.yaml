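# Adult reference population derived from published CDC anchor points:
# sd_female = 10.6/1.64, sd_male = 11.7/1.64, female median 163 cm,
# male 3rd percentile 163 cm.
label: CDC (derived adult anchors)
mean_male: 176.4179
sd_male: 7.134146
mean_female: 163.0
sd_female: 6.463415
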