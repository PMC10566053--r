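"id","M0001","M0002","M0003","M0004","M0005","M0006","M0007","M0008","M0009","M0010","M0011","M0012","M0013","M0014","M0015","M0016","M0017","M0018","M0019","M0020","M0021","M0022","M0023","M0024","M0025"
"S0001",,,,,,,,192526.861942735,,,,142460.235328453,,,,,,,19746.4706964421,,,,,,
"S0002",,,,,,,,46093.4451944895,,,,49094.6606353346,,,,,51676.4462618463,227860.622683836,,33270.9056952002,,,,,43229.4524023511
"S0003",,,,,843448.733069711,44520.678705875,,47585.6608146172,90328.2057159795,,,141355.952415119,264726.5221687,,204252.659343668,,69571.8424653789,,,,,,83352.8747982444,,
"S0004",,23618.216528232,,,,,,20568.1380067063,123679.476332973,306749.132706034,,63012.21004825,,,,,28458.0185188733,,,44599.4954398239,,,19566.9017459338,357090.511719939,55610.6783906601
"S0005",,14279.2412569873,,,1653458.51315208,173040.65859144,,36741.1018403815,,,,37013.0408157216,,359449.635962809,171647.128160805,,,,,37619.9461082074,,,74538.3476767078,,69698.6381273621
"S0006",,,,,,,,220006.105707667,,,,480350.322150877,,,152797.365581882,,,,,,,,80766.1161544587,,51103.4806808578
"S0007",,44487.3713951037,,,,61252.5330488828,,29180.2855275947,,,,125082.43670227,,,,,41074.9348187835,,44961.3235660268,20104.9944149972,,,40762.5545732009,,
"S0008",,,,,,,,,,,,113410.884156425,,,,,,,,,,,67221.6579239217,,
"S0009",,,,,664644.087103064,,,50512.2359185254,,,,81145.4769917789,,,49852.8146005532,,,288982.995724809,,,130501.816254297,,,,
"S0010",,,,,,,,11802.6777110659,218892.948546599,289932.735387509,,467203.132692161,,,159357.859714045,,46948.8948829646,62080.4525714178,,,,,239790.613832774,,30135.6419562375
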