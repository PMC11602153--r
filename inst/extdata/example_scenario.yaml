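# Example scenario configuration for `dusprofiler.R run-scenario` /
# readScenarioConfig(). Unset fields fall back to the packaged defaults.
scenario: knockout_panel
seed: 7
n_trnas: 10
replicates: 5
aas:
  moleculesPerTrna: 300
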