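# Fitted invalid-cue-condition model profile (attentional gain fixed at 1).
profile: invalid
sigma_c: 2.92
sigma_s: 15.7
B: 0.490
tau: 2.41
gamma: 0.212
bound: 353.5
noise_sd: 9.80
gain: 1
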