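species,max_height_m,sdmc,leaf_n,light_class_override,true_pft
Heinsenia diervilleoides,25.601254070177674,0.5445382463118001,18.178134636982744,NA,2
Strombosia scheffleri,35.592943453229964,0.5305863698997711,18.44142907520906,NA,1
Entandophrangma excelsum,43.57970641180873,0.5388134643185707,18.54691425844586,NA,1
Garcinia tansaniensis,30.902614103397354,0.5638232554300848,17.56329647937716,NA,2
Leptonychia usambarensis,11.74495509150438,0.5612508152560189,16.90605107525197,NA,5
Ocotea usambarensis,47.5325968968682,0.5123716897616251,19.120041470751026,NA,1
Cyathea manniana,12.699992921901867,0.3043859885698337,31.09844315760896,NA,6
Tabernaemontana stapfiana,21.82951025851071,0.4500039870081388,24.360205246825362,NA,3
Polyscias albersiana,22.65871879993938,0.34408971508655967,29.882964915498892,NA,4
Ficus sur,20.27909179008566,0.4238245850883299,24.102477791829287,NA,3
Syzygium guineense,25.134626019978896,0.4574794717616322,22.16422324239846,NA,3
Neoboutonia macrocalyx,24.570872138720006,0.3540643068317014,28.90674486307157,NA,4
Rauvolfia caffra,20.519874142017215,0.46648382280279654,23.8420163578084,NA,3
Albizia gummifera,26.27975345076993,0.4612877019324256,24.05446862571116,NA,3
Macaranga kilimandscharica,26.941401228308678,0.3491087496891633,30.07240272763244,NA,4
Vernonia auriculifera,12.481335386168212,0.3448314680874131,30.258207973313166,NA,6
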