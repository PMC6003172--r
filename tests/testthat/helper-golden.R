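# accuracy of the seed-97 ssGBLUP scenario, frozen after its first run;
# any change in the pipeline that alters the number stream or the algebra
# will be caught here
GOLDEN_SSGBLUP_ACCURACY <- 0.656056636304467
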