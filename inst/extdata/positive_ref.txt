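ORG0001
ORG0005
ORG0006
ORG0007
ORG0008
ORG0011
ORG0012
ORG0013
ORG0015
ORG0018
ORG0019
ORG0020
ORG0022
ORG0023
ORG0027
ORG0028
ORG0030
ORG0031
ORG0032
ORG0034
ORG0035
ORG0036
ORG0037
ORG0038
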