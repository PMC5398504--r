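{
 "is605I_left": {
  "T12": true,
  "T13": true,
  "T14": true,
  "T15": true,
  "T17": false,
  "T18A": true,
  "T18B": true,
  "T18C": true,
  "T18D": false,
  "T19": true,
  "T20": true,
  "T6": true,
  "T7A": true,
  "T8A": true,
  "T8B": true,
  "T9A": true
 },
 "is605I_right": {
  "T12": true,
  "T13": true,
  "T14": false,
  "T15": true,
  "T17": true,
  "T18A": true,
  "T18B": true,
  "T18C": true,
  "T18D": true,
  "T19": true,
  "T20": true,
  "T6": true,
  "T7A": true,
  "T8A": true,
  "T8B": true,
  "T9A": true
 },
 "isl3_left": {
  "1160_Fn": true,
  "1322_Fn": false,
  "1405_Fn": false,
  "1408_Fn": true,
  "1532_Fn": true,
  "343_Fn": true,
  "999_Fn": true,
  "T10": true,
  "T13B": true,
  "T13C": true,
  "T1A": true,
  "T1B": true,
  "T1C": true,
  "T2": true,
  "T3": true,
  "T4": true,
  "T5A": true,
  "T5B": true,
  "T6": true,
  "T7": true
 },
 "isl3_right": {
  "1160_Fn": true,
  "1322_Fn": true,
  "1405_Fn": true,
  "1408_Fn": true,
  "1532_Fn": true,
  "343_Fn": true,
  "999_Fn": true,
  "T13B": true,
  "T13C": false,
  "T1A": true,
  "T1B": true,
  "T1C": true,
  "T2": true,
  "T3": true,
  "T4": true,
  "T5A": true,
  "T6": true,
  "T7": true
 },
 "typeC_left": {
  "1012_Fp": true,
  "43_Fi": true,
  "687_Fp": true,
  "T1": true,
  "T12A": false,
  "T12B": false,
  "T12C": false,
  "T2": true,
  "T3": true,
  "T6": false,
  "T7": false
 },
 "typeC_right": {
  "1012_Fp": true,
  "43_Fi": false,
  "687_Fp": true,
  "T1": true,
  "T12A": false,
  "T12B": false,
  "T12C": false,
  "T2": true,
  "T3": true,
  "T6": false,
  "T7": true
 },
 "typeD_left": {
  "11_Ft": true,
  "29_Ft": true,
  "3_Ft": true,
  "T1": true,
  "T10": true,
  "T12": true,
  "T13A": true,
  "T13B": true,
  "T15A": true,
  "T15B": true,
  "T17": true,
  "T18": true,
  "T19": true,
  "T20": true,
  "T23": true,
  "T25": true,
  "T2A": true,
  "T2B": true,
  "T3": true,
  "T4A": true,
  "T4B": true,
  "T4C": true,
  "T5A": true,
  "T5B": true,
  "T5C": true,
  "T6A": true,
  "T6B": true,
  "T6C": true,
  "T7A": true,
  "T7B": true,
  "T9A": true,
  "T9B": true
 },
 "typeD_right": {
  "11_Ft": true,
  "29_Ft": true,
  "3_Ft": true,
  "T1": true,
  "T10": true,
  "T12": true,
  "T13A": true,
  "T13B": true,
  "T15A": true,
  "T15B": true,
  "T17": true,
  "T18": true,
  "T19": true,
  "T20": true,
  "T23": true,
  "T25": true,
  "T2A": true,
  "T2B": true,
  "T3": true,
  "T4A": true,
  "T4B": true,
  "T4C": true,
  "T5A": true,
  "T5B": true,
  "T5C": true,
  "T6A": true,
  "T6B": true,
  "T6C": true,
  "T7A": true,
  "T7B": true,
  "T9A": true,
  "T9B": true
 }
}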