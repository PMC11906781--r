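{
  "description": "Compact curated pathway library covering five metabolic pathways relevant to oxidative-stress cell metabolomics. Member lists are small HMDB-coded subsets; ids in the HMDB09xxxxx range are synthetic background identifiers used only to pad the universe.",
  "pathways": {
    "sphingolipid": {
      "name": "Sphingolipid metabolism",
      "members": ["HMDB0011773", "HMDB0000277", "HMDB0000224", "HMDB0000269",
                  "HMDB0000252", "HMDB0004949", "HMDB0000187", "HMDB0001383",
                  "HMDB0010169", "HMDB0006752"]
    },
    "taurine_hypotaurine": {
      "name": "Taurine and hypotaurine metabolism",
      "members": ["HMDB0000965", "HMDB0000251", "HMDB0000574", "HMDB0000996",
                  "HMDB0002757", "HMDB0000045"]
    },
    "nitrogen": {
      "name": "Nitrogen metabolism",
      "members": ["HMDB0000148", "HMDB0000641", "HMDB0000051", "HMDB0001096",
                  "HMDB0000595"]
    },
    "cysteine_methionine": {
      "name": "Cysteine and methionine metabolism",
      "members": ["HMDB0000192", "HMDB0005765", "HMDB0000574", "HMDB0000696",
                  "HMDB0001257", "HMDB0000742", "HMDB0001413", "HMDB0000099"]
    },
    "glycerophospholipid": {
      "name": "Glycerophospholipid metabolism",
      "members": ["HMDB0000086", "HMDB0000224", "HMDB0000564", "HMDB0000114",
                  "HMDB0001565", "HMDB0000097", "HMDB0001338"]
    }
  },
  "universe_extra": ["HMDB0900001", "HMDB0900002", "HMDB0900003", "HMDB0900004",
    "HMDB0900005", "HMDB0900006", "HMDB0900007", "HMDB0900008", "HMDB0900009",
    "HMDB0900010", "HMDB0900011", "HMDB0900012", "HMDB0900013", "HMDB0900014",
    "HMDB0900015", "HMDB0900016", "HMDB0900017", "HMDB0900018", "HMDB0900019",
    "HMDB0900020", "HMDB0900021", "HMDB0900022", "HMDB0900023", "HMDB0900024",
    "HMDB0900025", "HMDB0900026", "HMDB0900027", "HMDB0900028", "HMDB0900029",
    "HMDB0900030", "HMDB0900031", "HMDB0900032", "HMDB0900033", "HMDB0900034",
    "HMDB0900035", "HMDB0900036", "HMDB0900037", "HMDB0900038", "HMDB0900039",
    "HMDB0900040", "HMDB0900041", "HMDB0900042", "HMDB0900043", "HMDB0900044",
    "HMDB0900045", "HMDB0900046", "HMDB0900047", "HMDB0900048", "HMDB0900049",
    "HMDB0900050", "HMDB0900051", "HMDB0900052", "HMDB0900053", "HMDB0900054",
    "HMDB0900055", "HMDB0900056", "HMDB0900057", "HMDB0900058", "HMDB0900059",
    "HMDB0900060"]
}
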