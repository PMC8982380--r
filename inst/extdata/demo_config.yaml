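# Demo pipeline configuration: one screening round of four experimental
# clones, one of which stabilizes the reporter in 90% of VU-fated cells.
seed: 1
n_clones: 4
n_planted: 1
planted_penetrance: 0.9
n_animals: 20
method: top5
k: 5.0
f: 0.1
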