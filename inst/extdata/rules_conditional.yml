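# Label-conditional quality rewrites (off by default; enable explicitly).
# Patterns are token sequences, "*" is a gap of one or more tokens, matching
# runs on stems. The mirrored "decreased" patterns ship trigger-only: no
# curated target id is bundled, supply `replacement` to activate them.
rules:
  - kind: conditional
    pattern: increased activity
    trigger: PATO:0000470      # increased
    replacement: PATO:0000912  # increased rate
  - kind: conditional
    pattern: increased * number
    trigger: PATO:0000470      # increased
    replacement: PATO:0002001  # has extra parts of type
  - kind: conditional
    pattern: decreased activity
    trigger: PATO:0001997      # decreased
    replacement: null
  - kind: conditional
    pattern: decreased * number
    trigger: PATO:0001997      # decreased
    replacement: null
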