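time_s,fraction
35.072992700729941,0.077154304351759545
46.353194196558164,0.141377896950471649
61.261342325632754,0.138798929313123626
80.964259930484474,0.155004364896387137
107.004044267378887,0.226511751440485326
141.418763036998939,0.219480928404731102
186.901968760556571,0.284772911815898255
247.013516285903563,0.277109833824604523
326.458183573735369,0.336462497482706069
431.453902704289533,0.390258795801318115
570.218421609018719,0.470406180919931416
753.612486303389801,0.548717096761226708
995.989883858557960,0.615288620012657939
1316.320876813638506,0.672994353694402303
1739.676957383122499,0.781406259170824735
2299.193129395516735,0.831369104276299842
3038.661300780433976,0.887238973804016506
4015.957764839103220,0.994134727031902754
5307.573030541198932,0.995755991481611646
7014.598540145987499,0.973162051155599839
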