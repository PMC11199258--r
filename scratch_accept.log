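[ FAIL 0 | WARN 0 | SKIP 0 | PASS 36 ]
TOTAL: 4.5 min
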