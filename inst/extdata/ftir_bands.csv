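"label","low","high","annotation"
"3630",3630,3630,"nu(OH); pectin, phenolic compounds"
"3525",3525,3525,"nu(OH); pectin, phenolic compounds"
"3414",3414,3414,"nu(OH); pectin, phenolic compounds"
"3300",3300,3300,"nu(OH); water, carbohydrates (pectin and cellulose), organic acids, polyphenols"
"3078",3078,3078,"nu(C(sp3)-H); carbohydrates, carboxylic acids, flavonoid glycosides"
"3010",3010,3010,"nu(C(sp3)-H); carbohydrates, carboxylic acids, flavonoid glycosides"
"2962",2962,2962,"nu(C(sp3)-H); carbohydrates, carboxylic acids, flavonoid glycosides"
"2922",2922,2922,"nu(C(sp3)-H); carbohydrates, carboxylic acids, flavonoid glycosides"
"2850",2850,2850,"nu(C(sp3)-H); carbohydrates, carboxylic acids, flavonoid glycosides"
"1730",1730,1730,"nu(C=O); organic acids, esters, cutin"
"1643",1643,1643,"delta(OH), nu(C=O); polyphenols, carbohydrates, organic acids, water; flavonoids"
"1600",1600,1600,"nu(C-C), nu(COOH); pectin, aromatic compounds"
"1517",1517,1517,"nu(C=C-C) aromatic; phenolic compounds"
"1439",1439,1439,"delta(C-H), delta(O-H), nu(COOH); carbohydrates (e.g. pectin)"
"1400",1400,1400,"delta(C-H), delta(O-H), nu(COOH); carbohydrates (e.g. pectin)"
"1370-1360",1360,1370,"nu(CH3), nu(C-OOH); organic acids, carbohydrates"
"1330",1330,1330,"delta(C-H); polysaccharides (e.g. cellulose)"
"1300",1300,1300,"delta(C-H); polysaccharides (e.g. cellulose)"
"1280-1274",1274,1280,"delta(O-H), nu(C-N), delta(N-H), delta(O=C-N); cutin, polysaccharides, proteins (amide III)"
"1240",1240,1240,"nu(C-O), nu(C=C); polyphenols, carbohydrates, aromatic polyphenols"
"1200",1200,1200,"nu(C-O-C), nu(C-C); cellulose"
"1182",1182,1182,"nu(C-O-C), nu(C-C); cellulose"
"1147",1147,1147,"nu(C-O-C); cutin, pectin, cellulose"
"1093",1093,1093,"nu(C-O), nu(C-C); pectin, polysaccharides"
"1055",1055,1055,"delta(C-O), nu(C-OH); carbohydrates (cellulose, sucrose)"
"1016-1012",1012,1016,"nu(C-O), nu(C-C), delta(C-OH), delta(O-CH); pectin, cellulose, carboxylic acids, alcohols"
"975",975,975,"delta(trans C-H); carotenoids"
"920",920,920,"delta(C=C), delta(C-H); alkenes, benzene ring of phenols"
"890",890,890,"delta(C-H); para (1,4)-substituted aromatic rings"
"842",842,842,"delta(C-H); para (1,4)-substituted aromatic rings"
"812",812,812,"C-H; aromatic ring of phenols"
"765",765,765,"delta(OH), delta(C-H); C-OH group, ortho (1,2)-substituted aromatic rings"
"738",738,738,"delta(cis C-H); carotenoids"
"669",669,669,"delta(O-H); pectin"
"623",623,623,"delta(O-H); pectin"
"586",586,586,"delta(C-H); polyphenols and flavonoids"
"530-524",524,530,"delta(C-O-C); glycosidic bond of pectin"
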