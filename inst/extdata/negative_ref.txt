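OTH0001
OTH0002
OTH0003
OTH0005
OTH0006
OTH0008
OTH0009
OTH0010
OTH0012
OTH0014
OTH0018
OTH0021
OTH0022
OTH0025
OTH0030
OTH0031
OTH0032
OTH0033
OTH0034
OTH0035
OTH0036
OTH0037
OTH0039
OTH0040
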