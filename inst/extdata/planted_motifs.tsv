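protein_id	motif_type	start	end
SYN0001	Cx3C	24	28
SYN0001	Cx3C	50	54
SYN0002	Cx9C	20	30
SYN0002	Cx9C	38	48
SYN0003	Cx9C	27	37
SYN0003	Cx9C	59	69
SYN0004	Cx3C	16	20
SYN0004	Cx3C	38	42
SYN0005	Cx3C	29	33
SYN0005	Cx3C	58	62
SYN0006	Cx9C	18	28
SYN0006	Cx9C	46	56
SYN0007	Cx9C	21	31
SYN0007	Cx9C	37	47
SYN0008	Cx9C	9	19
SYN0008	Cx9C	33	43
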