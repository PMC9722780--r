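# Fitted valid-cue-condition model profile (attentional gain free).
profile: valid
sigma_c: 2.94
sigma_s: 16.9
B: 0.505
tau: 2.38
gamma: 0.207
bound: 356.0
noise_sd: 10.6
gain: 1.20
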