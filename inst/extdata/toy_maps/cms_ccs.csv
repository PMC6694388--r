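cc
CC01
CC02
CC03
CC04
CC05
CC07
CC08
CC10
CC11
CC12
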