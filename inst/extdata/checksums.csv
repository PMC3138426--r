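file,md5
fleming_cohort.csv,3df00d535cdabf1cd478d190ed608191
gehan_cohort.csv,73495ce8671df376f665cebf040c11d8
thresholds_fleming.csv,4a0f629cd60c8b693946913e69ea0639
thresholds_gehan_epd_0.4_0.6.csv,b4c1ba8feeb5a8738151e2c7e2fb030d
thresholds_gehan_epd_0.3_0.5.csv,3fa1175c906b5b29b2e35b2ddc8a8043
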