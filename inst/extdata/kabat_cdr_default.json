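{
  "_comment": "Standard Kabat heavy-chain CDR boundaries plus the non-canonical CDR4 loop (residues 71-78). CDR1-3 bounds are the standard Kabat definitions; override per analysis if a different scheme is required. Inserted positions (35a, 52a, 82a-c, 100a-k) inherit the region of their parent number.",
  "cdr1": ["31", "35"],
  "cdr2": ["50", "65"],
  "cdr3": ["95", "102"],
  "cdr4": ["71", "78"]
}
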