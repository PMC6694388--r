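code,cc
C01,CC01
C02,CC02
C03,CC03
C04,CC04
C05,CC05
C06,CC06
C07,CC07
C08,CC08
C09,CC09
C10,CC01
C11,CC02
C12,CC03
C13,CC04
C14,CC05
C15,CC06
C16,CC07
C17,CC08
C18,CC09
C19,CC01
C20,CC02
C21,CC03
C22,CC04
C23,CC05
C24,CC06
C25,CC07
C26,CC08
C27,CC09
C28,CC01
C29,CC02
C30,CC03
C31,CC04
C32,CC05
C33,CC06
C34,CC07
C35,CC08
C36,CC09
C37,CC01
C38,CC02
C39,CC03
C40,CC04
C41,CC05
C42,CC06
C43,CC07
C44,CC08
C45,CC09
C46,CC01
C47,CC02
C48,CC03
C49,CC04
C50,CC05
C51,CC06
C52,CC07
C53,CC08
C54,CC09
C55,CC01
C56,CC02
C57,CC03
AMI_P,CC10
HF_P,CC11
PN_P,CC12
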