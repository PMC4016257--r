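# Quality rewrites applied to every generated EQ statement.
# "absent" is conventionally curated as "lacks all parts of type".
rules:
  - kind: unconditional
    trigger: PATO:0000462      # absent
    replacement: PATO:0002000  # lacks all parts of type
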