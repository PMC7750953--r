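# Example configuration for `puma simulate --config example_config.yaml --out DIR`
# All fields optional; these are the defaults of simulate_config().
m: 20              # regulators (miRNAs)
n: 60              # target genes
tissues: 4
samples: 100       # per tissue
density: 0.05      # background prior edge density
discordance: 0.2   # fraction of cells resampled in the second prior
beta: 2            # module loading on the latent regulator activity
sigma: 1           # expression noise sd
prior_dropout: 0.3 # fraction of planted edges removed from the prior
seed: 1
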