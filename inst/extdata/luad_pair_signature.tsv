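pair	coef	hr	hr95l	hr95h	p
LINC00958|HIF1A-AS3	-0.559056064	0.571748503	0.404824948	0.807500506	0.00150468
ITGB1-DT|FENDRR	0.372948657	1.452009787	1.060841449	1.9874152	0.019871749
AC004264.1|LINC02036	0.39121285	1.478773237	1.076738936	2.030919672	0.015661584
AC026355.2|AL049836.1	-0.42262269	0.655325847	0.480477131	0.893803134	0.00760824
LINC02195|LINC01116	-0.513869512	0.598176444	0.437208026	0.81840917	0.00131407
LINC02362|LINC00941	-0.534861917	0.585750167	0.411859423	0.833059143	0.002916854
LINC01116|LINC02154	0.621835544	1.86234332	1.229948538	2.819892489	0.003305756
AL606489.1|AC006017.1	0.443770725	1.558573103	1.084414844	2.240056129	0.016491365
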