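sample_id,value
rat_01,-1.785038
rat_02,-4.111573
rat_03,-8.440754
rat_04,-8.204876
rat_05,14.81101
rat_06,-11.495773
rat_07,2.979702
rat_08,-17.843026
rat_09,-11.052978
rat_10,-7.131784
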