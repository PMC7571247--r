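# Orthonormal lowpass decomposition filters, one per line: family order coefficients...
daubechies 1 0.70710678118654757 0.70710678118654757
daubechies 2 -0.12940952255126037 0.22414386804201339 0.83651630373780794 0.48296291314453416
daubechies 3 0.035226291885709533 -0.085441273882026658 -0.13501102001025458 0.45987750211849154 0.80689150931109255 0.33267055295008263
daubechies 4 -0.010597401785069032 0.032883011666885197 0.030841381835560764 -0.18703481171909309 -0.027983769416859854 0.63088076792985892 0.71484657055291567 0.23037781330889651
daubechies 5 0.0033357252854737712 -0.012580751999081999 -0.0062414902127982744 0.077571493840045719 -0.032244869584638375 -0.24229488706638203 0.13842814590132074 0.72430852843777294 0.60382926979718965 0.16010239797419293
symlet 1 0.70710678118654757 0.70710678118654757
symlet 2 -0.12940952255092145 0.22414386804185735 0.83651630373746899 0.48296291314469025
symlet 3 0.035226291882100656 -0.085441273882241486 -0.13501102001039084 0.45987750211933132 0.80689150931333875 0.33267055295095688
symlet 4 -0.075765714789273325 -0.02963552764599851 0.49761866763201545 0.80373875180591614 0.29785779560527736 -0.099219543576847216 -0.012603967262037833 0.032223100604042702
symlet 5 0.027333068345077982 0.029519490925774643 -0.039134249302383094 0.1993975339773936 0.72340769040242059 0.63397896345821192 0.016602105764522319 -0.17532808990845047 -0.021101834024758855 0.019538882735286728
coiflet 1 -0.015655728135791993 -0.07273261951252645 0.38486484686485778 0.85257202021160039 0.33789766245748182 -0.07273261951252645
coiflet 2 -0.00072054944552034698 -0.0018232088709110323 0.0056114348193688343 0.02368017194684777 -0.059434418646431092 -0.076488599078280761 0.41700518442323908 0.81272363544941351 0.38611006682276289 -0.067372554723725595 -0.041464936786871777 0.016387336463203641
coiflet 3 -3.4599773197272781e-05 -7.0983302506379004e-05 0.00046621695982040288 0.0011175187708306303 -0.0025745176881367972 -0.0090079761367306242 0.015880544863669452 0.034555027573297738 -0.082301927106299827 -0.071799821619154838 0.42848347637737 0.79377722262608719 0.40517690240911824 -0.061123390002972552 -0.065771911281469364 0.023452696142077168 0.0077825964256727463 -0.0037935128643808019
coiflet 4 -1.7849909144933469e-06 -3.259647940030751e-06 3.1229861599195265e-05 6.2338854312787192e-05 -0.00025997433712225682 -0.00058902022463321654 0.0012665610789256603 0.0037514346971460866 -0.0056582838001308835 -0.015211728187697211 0.025082253337949612 0.039334422605589149 -0.096220424535952642 -0.066627472366817167 0.43438603311435653 0.78223893442428261 0.41530842700068227 -0.056077319603569258 -0.081266710249193727 0.02668230466960483 0.016068947131575029 -0.0073461679362680507 -0.001629492425226786 0.00089231390253700297
coiflet 5 -9.6040101127678941e-08 -1.6237995172048338e-07 2.0612203985788783e-06 3.7007277113394796e-06 -2.1270221672515614e-05 -4.1219861924265501e-05 0.00014035632812373243 0.00030185794166824478 -0.00063755892612588115 -0.0016616273039298788 0.0024315754425382886 0.0067615202206204169 -0.0091595073386761625 -0.019758391600965465 0.032674799467057355 0.041287530472117834 -0.10556315130733723 -0.06203775157498196 0.43798230665916338 0.77429362286032744 0.42157126673075435 -0.052046670253554764 -0.091921588060086087 0.028169744270532353 0.023408322118927783 -0.010131584846900276 -0.0041593126275786402 0.0021782943778456947 0.00035857774116175768 -0.000212081862067494
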