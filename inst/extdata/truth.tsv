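protein_id	class	true_effect
ORG0001	organellar	-1.9167159980852262
ORG0002	organellar	-2.4084618428147753
ORG0003	organellar	-1.5836191459061244
ORG0004	organellar	-1.4105529766897047
ORG0005	organellar	-0.9854732905436762
ORG0006	organellar	-1.195032395569085
ORG0007	organellar	-1.0583656748226768
ORG0008	organellar	-1.027699756366886
ORG0009	organellar	-1.2895556524265768
ORG0010	organellar	-2.2166273335338618
ORG0011	organellar	-1.3398123959099162
ORG0012	organellar	-1.292955157755783
ORG0013	organellar	-1.2772142131107227
ORG0014	organellar	-1.6883169407562402
ORG0015	organellar	-1.140185881767552
ORG0016	organellar	-1.7398923859887747
ORG0017	organellar	-1.9109729356298688
ORG0018	organellar	-1.6771125214628675
ORG0019	organellar	-1.765359781146468
ORG0020	organellar	-1.5430492086045324
ORG0021	organellar	-1.797445614023755
ORG0022	organellar	-0.5496244053576702
ORG0023	organellar	-1.3566003990354123
ORG0024	organellar	-1.3703340768768382
ORG0025	organellar	-1.627238688389815
ORG0026	organellar	-0.5237492091194597
ORG0027	organellar	-1.213044437128938
ORG0028	organellar	-1.4072946260014387
ORG0029	organellar	-1.996705337045786
ORG0030	organellar	-2.1446608051458784
ORG0031	organellar	-1.4636264263622112
ORG0032	organellar	-1.9038568383971735
ORG0033	organellar	-1.980743067388369
ORG0034	organellar	-1.4794640940021728
ORG0035	organellar	-1.8543849317016314
ORG0036	organellar	-1.0103535411455278
ORG0037	organellar	-2.2165552833725175
ORG0038	organellar	-1.7520639805342044
ORG0039	organellar	-1.5654060108563044
ORG0040	organellar	-1.6697569527674752
OTH0001	other	0
OTH0002	other	0
OTH0003	other	0
OTH0004	other	0
OTH0005	other	0
OTH0006	other	0
OTH0007	other	0
OTH0008	other	0
OTH0009	other	0
OTH0010	other	0
OTH0011	other	0
OTH0012	other	0
OTH0013	other	0
OTH0014	other	0
OTH0015	other	0
OTH0016	other	0
OTH0017	other	0
OTH0018	other	0
OTH0019	other	0
OTH0020	other	0
OTH0021	other	0
OTH0022	other	0
OTH0023	other	0
OTH0024	other	0
OTH0025	other	0
OTH0026	other	0
OTH0027	other	0
OTH0028	other	0
OTH0029	other	0
OTH0030	other	0
OTH0031	other	0
OTH0032	other	0
OTH0033	other	0
OTH0034	other	0
OTH0035	other	0
OTH0036	other	0
OTH0037	other	0
OTH0038	other	0
OTH0039	other	0
OTH0040	other	0
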