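code
C07
C14
C21
C28
C35
C42
C49
C56
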