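# synthetic representative sloping high-frequency loss (not measured data)
# frequency_hz  threshold_db_hl
250 20
500 30
1000 40
2000 55
3000 65
4000 70
6000 75
8000 80
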