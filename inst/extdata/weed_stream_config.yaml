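# Synthetic weed-classification stream: a camera pass over two plants.
# Phases: confident misclassification of the first plant's base, noisy
# correct classification of its leaves, a transition as the camera moves,
# then the second plant. Spikes model isolated adversarial frames.
segments:
  - start: 0
    end: 50
    scores: {Ragweed: 0.20, Pigweed: 0.70, Cocklebur: 0.00}
  - start: 50
    end: 120
    scores: {Ragweed: 0.80, Pigweed: 0.15, Cocklebur: 0.00}
  - start: 120
    end: 150
    scores: {Ragweed: 0.45, Pigweed: 0.45, Cocklebur: 0.00}
  - start: 150
    end: 200
    scores: {Ragweed: 0.10, Pigweed: 0.85, Cocklebur: 0.00}
noise_sd: 0.05
spike_prob: 0.02
spike_target: Cocklebur
spike_value: 0.9
seed: 42
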