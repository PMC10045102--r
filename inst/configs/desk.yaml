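# Desk-scale simulation preset: ten heterogeneous sites, 50 training and
# 20 validation slices each, acceleration 4 with an 8% ACS region.
clients: 10
iid: false
seed: 1
rounds: 20
total_steps: 400
algo: scaffold
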