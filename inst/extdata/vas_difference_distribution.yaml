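# Illustrative distribution of pain-VAS change scores (baseline minus
# post-treatment), support -1..6 with median 1.5 under the midpoint
# convention. Not empirical trial frequencies.
support: [-1, 0, 1, 2, 3, 4, 5, 6]
probabilities: [0.20, 0.10, 0.20, 0.15, 0.12, 0.10, 0.08, 0.05]
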