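# Example codebook override for pdmedalg (read with read_codebook()).
# Any key present here replaces/merges over the built-in defaults; see
# ?default_codebook for the full schema. Code sets below are synthetic
# examples, not an authoritative ATC/ICD-10 list.
quetiapine_max_mg: 50
dx_sets:
  rls: ["G25.81"]          # use the 4-character RLS code
  tremor_nos: ["R25.1"]    # conventional tremor-NOS coding
apm_classes:
  anticholinergic: ["N04AA01", "N04AA02", "N04AA04", "N04AC01"]
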